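test_that("the pressure-shear set point has the 1.4 Pa floor and the 10 Pa
           ceiling", {
  expect_identical(tau_e(mmHg_to_Pa(10)), 1.4)
  expect_identical(tau_e(mmHg_to_Pa(5)), 1.4)
  expect_identical(tau_e(0), 1.4)
  # frozen evaluation of the sigmoid at 25 mmHg
  expect_equal(tau_e(mmHg_to_Pa(25)), 2.60343017352, tolerance = 1e-9)
  expect_equal(tau_e(mmHg_to_Pa(1e6)), 10, tolerance = 1e-6)
  # monotone over the physiological range
  P <- mmHg_to_Pa(seq(10, 100, by = 5))
  expect_true(all(diff(tau_e(P)) > 0))
})

test_that("stimulus terms evaluate their calibrated forms", {
  par <- adaptation_params(Q_ref = 4.87e-12)
  st0 <- stimuli(tau_w = 0, Pb_bar = 2660, Q = 1e-13, H = 0.45, par)
  expect_equal(st0$S_wss, log10(0.103), tolerance = 1e-12)
  # metabolic term at the reference red-cell flux
  st1 <- stimuli(tau_w = 1, Pb_bar = 2660, Q = 4.87e-12 / 0.45, H = 0.45,
                 par)
  expect_equal(st1$S_m, 0.07 * log10(2), tolerance = 1e-12)
  # the pressure stimulus vanishes when the set point is unity
  par1 <- adaptation_params(Q_ref = 1e-12, stress_scale = 1)
  # tau_e floors at 1.4 Pa, so feed the identity through the formula
  expect_equal(stimuli(0, 2660, 1e-13, 0.45, par1)$S_p,
               -par1$k_p * log10(tau_e(2660)))
  # S_tot assembles the four contributions
  st <- stimuli(0.5, 2660, 1e-13, 0.45, par)
  expect_equal(st$S_tot, st$S_wss + st$S_p + st$S_m - par$k_s)
  expect_error(stimuli(1, 2660, 1e-13, 0.45,
                       adaptation_params(Q_ref = -1)), "Q_ref")
})

test_that("one remodeling step matches a term-by-term spreadsheet
           evaluation", {
  dom <- small_domain(); tis <- tissue_properties()
  net <- chain_network(3, D = c(10e-6, 12e-6, 14e-6))
  net$segments$D <- c(10e-6, 12e-6, 14e-6)
  net <- solve_nodal_pressures(net, dom, tis, Pi = 0, leakage = FALSE)
  par <- adaptation_params(Q_ref = 4.87e-12)
  out <- update_diameters(net, par)
  # independent spreadsheet-style evaluation
  sg <- net$segments
  fi <- match(sg$from, net$nodes$id); ti <- match(sg$to, net$nodes$id)
  Pb <- (net$nodes$pressure[fi] + net$nodes$pressure[ti]) / 2
  te <- ifelse(Pa_to_mmHg(Pb) > 10,
               0.1 * (100 - 86 * exp(-5000 *
                 (log10(log10(Pa_to_mmHg(Pb))))^5.4)), 1.4)
  S <- log10(10 * abs(sg$tau_w) + 0.103) - 0.1 * log10(te) +
    0.07 * log10(4.87e-12 / pmax(abs(sg$Q) * sg$H, 1e-30 * 4.87e-12) + 1) -
    0.35
  D_exp <- pmin(pmax(sg$D + sg$D * 0.1 * S, 4e-6), 24e-6)
  expect_equal(out$segments$D, D_exp, tolerance = 1e-12)
})

test_that("diameters stay clamped, the parent never remodels, and zero
           stimulus means zero change", {
  dom <- small_domain(); tis <- tissue_properties()
  net <- chain_network(4)
  net$segments$is_parent <- c(TRUE, FALSE, FALSE, FALSE)
  net$segments$D <- c(28e-6, 24e-6, 4e-6, 12e-6)
  net$segments$mu <- 2e-3
  net <- solve_nodal_pressures(net, dom, tis, Pi = 0, leakage = FALSE)
  par <- adaptation_params(Q_ref = 1e-13)
  out <- update_diameters(net, par)
  expect_equal(out$segments$D[1], 28e-6)     # parent fixed
  expect_true(all(out$segments$D[-1] >= 4e-6 &
                  out$segments$D[-1] <= 24e-6))
  # a segment at the upper clamp with positive stimulus stays there
  st <- attr(out, "stimuli")
  if (st$S_tot[2] > 0) expect_equal(out$segments$D[2], 24e-6)

  # switching off every sensitivity and the shrink tendency with a shear
  # stimulus of exactly one leaves diameters untouched
  par0 <- adaptation_params(tau_ref = 1, k_p = 0, k_m = 0, k_s = 0,
                            Q_ref = 1e-13, stress_scale = 1)
  net0 <- net
  net0$segments$Q <- 0
  net0$segments$tau_w <- 0
  out0 <- update_diameters(net0, par0)
  expect_equal(out0$segments$D, net0$segments$D)  # S_tot = log10(1) = 0
  expect_equal(attr(out0, "max_rel_dD"), 0)
})

test_that("a single vessel remodels to the same fixed point from both
           sides", {
  dom <- small_domain(); tis <- tissue_properties()
  par <- adaptation_params(Q_ref = 4.87e-12)
  relax_to_steady <- function(D0) {
    net <- chain_network(1, D = D0, mu = 2e-3)
    net$segments$D <- D0
    for (i in 1:600) {
      net$segments$mu <- apparent_viscosity(net$segments$D, 0.45)
      net <- solve_nodal_pressures(net, dom, tis, Pi = 0, leakage = FALSE)
      net <- update_diameters(net, par)
      if (attr(net, "max_rel_dD") < 1e-7) break
    }
    net$segments$D
  }
  from_low <- relax_to_steady(6e-6)
  from_high <- relax_to_steady(22e-6)
  expect_equal(from_low, from_high, tolerance = 1e-4)
})

test_that("without the metabolic stimulus, low-flow distal branches shrink
           to the 4 um bound", {
  dom <- small_domain(); tis <- tissue_properties()
  # low-perfusion Y tree (millimetric branches, 100 Pa drive): shear alone
  # cannot sustain it
  net <- y_network(D_feed = 16e-6, D1 = 14e-6, D2 = 6e-6, L = 2e-3)
  par <- adaptation_params(k_m = 0, Q_ref = 4.87e-12)
  for (i in 1:400) {
    net$segments$mu <- apparent_viscosity(net$segments$D, 0.45)
    net <- solve_nodal_pressures(net, dom, tis, Pi = 0,
                                 P_inlet = 1430, P_outlet = 1330,
                                 leakage = FALSE)
    net <- update_diameters(net, par)
    if (attr(net, "max_rel_dD") < 1e-8) break
  }
  # the weakly perfused narrow daughter regresses fully
  expect_equal(min(net$segments$D), 4e-6, tolerance = 1e-6)
})
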