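#' Transport properties of normal and tumor tissue
#'
#' Per-region material properties of the interstitium and of the vessel
#' wall, converted to SI on construction. Defaults are the standard solid
#' tumor / normal tissue set used throughout the package: tumor vessels are
#' roughly an order of magnitude leakier (`Lp`) and the tumor interstitium
#' about five times more conductive (`K`) than normal tissue, with a larger
#' exchange area (`S/V`), a lower osmotic reflection coefficient and a
#' higher interstitial oncotic pressure.
#'
#' @param Lp hydraulic conductivity of the vessel wall, cm/(mmHg s),
#'   named vector for regions `normal` and `tumor`.
#' @param K hydraulic conductivity of the interstitium, cm^2/(mmHg s).
#' @param SV exchange surface area per unit tissue volume, 1/cm.
#' @param pi_B plasma oncotic pressure, mmHg.
#' @param pi_i interstitial oncotic pressure, mmHg.
#' @param sigma osmotic reflection coefficient for plasma proteins.
#' @return object of class `tissue_properties`: list with per-region SI
#'   fields `Lp` (m/Pa/s), `K` (m^2/Pa/s), `SV` (1/m), `pi_B`, `pi_i` (Pa),
#'   `sigma`, and the derived effective oncotic jump `sigma_dpi` (Pa).
#' @export
tissue_properties <- function(Lp = c(normal = 0.36e-7, tumor = 2.80e-7),
                              K = c(normal = 8.53e-9, tumor = 4.13e-8),
                              SV = c(normal = 70, tumor = 200),
                              pi_B = c(normal = 20, tumor = 20),
                              pi_i = c(normal = 10, tumor = 15),
                              sigma = c(normal = 0.91, tumor = 0.82)) {
  regions <- c("normal", "tumor")
  chk <- function(x, nm) {
    if (!all(regions %in% names(x))) {
      stop(sprintf("'%s' must be named for regions 'normal' and 'tumor'", nm))
    }
    x[regions]
  }
  Lp <- chk(Lp, "Lp"); K <- chk(K, "K"); SV <- chk(SV, "SV")
  pi_B <- chk(pi_B, "pi_B"); pi_i <- chk(pi_i, "pi_i"); sigma <- chk(sigma, "sigma")
  if (any(sigma < 0 | sigma > 1)) stop("sigma must lie in [0, 1]")
  if (any(c(Lp, K, SV) <= 0)) stop("Lp, K and S/V must be positive")
  props <- list(
    Lp = lp_cgs_to_si(Lp),
    K = k_cgs_to_si(K),
    SV = sv_cgs_to_si(SV),
    pi_B = mmHg_to_Pa(pi_B),
    pi_i = mmHg_to_Pa(pi_i),
    sigma = sigma
  )
  props$sigma_dpi <- props$sigma * (props$pi_B - props$pi_i)
  class(props) <- "tissue_properties"
  props
}

#' Apparent blood viscosity law constants
#'
#' Constants of the empirical in-vitro law for the relative apparent
#' viscosity of blood in narrow tubes as a function of diameter and
#' discharge hematocrit.
#'
#' @param mu_plasma plasma viscosity, Pa s.
#' @param mu_parent apparent viscosity used for parent-vessel segments,
#'   Pa s. Kept as an explicit constant (rather than the law evaluated at
#'   28 um, H = 0.45) so that the parent reference flow matches the
#'   conventional parent operating point; see the methods vignette.
#' @return object of class `viscosity_law`.
#' @export
viscosity_law <- function(mu_plasma = 1.2e-3, mu_parent = 0.0031) {
  stopifnot(mu_plasma > 0, mu_parent > 0)
  structure(list(mu_plasma = mu_plasma, mu_parent = mu_parent),
            class = "viscosity_law")
}

#' Phase-separation (plasma skimming) parameters
#'
#' @param zeta strength of the asymmetry of the red-cell split at a
#'   bifurcation (0 = proportional split).
#' @param U_cr critical ratio of daughter-branch velocities above which the
#'   slower branch receives no red cells.
#' @param H_parent discharge hematocrit held fixed in the parent vessel.
#' @param H_max clamp on segment hematocrit.
#' @return object of class `phase_sep_params`.
#' @export
phase_sep_params <- function(zeta = 0.5, U_cr = 2.5, H_parent = 0.45,
                             H_max = 0.95) {
  stopifnot(zeta >= 0, U_cr > 1, H_parent > 0, H_parent < 1,
            H_max > 0, H_max <= 1)
  structure(list(zeta = zeta, U_cr = U_cr, H_parent = H_parent, H_max = H_max),
            class = "phase_sep_params")
}

#' Structural adaptation parameters
#'
#' Sensitivities and bounds of the diameter-remodeling law. The total
#' stimulus is
#' `S_tot = log10(tau_w + tau_ref) - k_p*log10(tau_e(P_b)) +
#'  k_m*log10(Q_ref/(Q_b*H) + 1) - k_s`
#' and one remodeling step changes each capillary diameter by
#' `dD = D * dt * S_tot`, clamped to `D_bounds`.
#'
#' @param tau_ref offset avoiding a singular wall-shear stimulus at zero
#'   shear, Pa.
#' @param k_p sensitivity to the pressure-derived shear set point, 1/s.
#' @param k_m sensitivity of the metabolic stimulus, 1/s.
#' @param k_s intrinsic shrinking tendency, 1/s.
#' @param Q_ref reference (parent-vessel) flow, m^3/s; `NA` means "use the
#'   largest segment flow in the network at each step".
#' @param dt remodeling time step, s.
#' @param D_bounds allowed capillary diameter range, m.
#' @param max_steps cap on remodeling steps when iterated to steady state.
#' @param tol_D steady-state tolerance on max |dD/D|.
#' @param Qh_floor_frac metabolic stimulus for stagnant segments
#'   (`Q_b*H < Qh_floor_frac*Q_ref`) is evaluated at `Qh_floor_frac*Q_ref`
#'   to keep the logarithm bounded.
#' @param stress_scale factor applied to the wall shear stress (Pa)
#'   before it enters the shear-stimulus logarithm. The default 10
#'   evaluates that logarithm in dyn/cm2, the unit in which the
#'   `tau_ref = 0.103` offset was originally calibrated; on that scale
#'   flow-carrying capillaries dilate while stagnant ones regress, the
#'   behavior the remodeling model is meant to produce. Evaluating it in
#'   Pa (`stress_scale = 1`) shifts the shear stimulus down by one unit
#'   and makes every vessel of a capillary bed at these driving pressures
#'   shrink to the lower bound. The pressure stimulus uses the shear set
#'   point in Pa (its printed sigmoid spans 1.4-10 Pa) and is not
#'   affected. See the methods vignette.
#' @return object of class `adaptation_params`.
#' @export
adaptation_params <- function(tau_ref = 0.103, k_p = 0.1, k_m = 0.07,
                              k_s = 0.35, Q_ref = NA_real_, dt = 0.1,
                              D_bounds = c(4e-6, 24e-6), max_steps = 2000,
                              tol_D = 1e-4, Qh_floor_frac = 1e-30,
                              stress_scale = 10) {
  stopifnot(tau_ref > 0, k_p >= 0, k_m >= 0, k_s >= 0, dt >= 0,
            length(D_bounds) == 2, D_bounds[1] < D_bounds[2],
            Qh_floor_frac > 0, stress_scale > 0)
  structure(list(tau_ref = tau_ref, k_p = k_p, k_m = k_m, k_s = k_s,
                 Q_ref = Q_ref, dt = dt, D_bounds = D_bounds,
                 max_steps = max_steps, tol_D = tol_D,
                 Qh_floor_frac = Qh_floor_frac, stress_scale = stress_scale),
            class = "adaptation_params")
}

#' Iterative solver settings
#'
#' @param omega_net SOR relaxation factor for the nodal (network) solve.
#' @param omega_grid SOR relaxation factor for the interstitial grid solve.
#' @param tol relative-change convergence tolerance of the inner solves
#'   (kept well below the outer tolerances so that discrete conservation
#'   holds at the flow level).
#' @param max_sweeps cap on SOR sweeps.
#' @param outer_tol_P relative-error threshold on P_b and P_i in the outer
#'   (coupling) loop.
#' @param outer_tol_DH relative-error threshold on D and H in the outer loop.
#' @param max_outer cap on outer coupling iterations. The coupled
#'   pressure fields are stationary to about 1e-4 within tens of
#'   iterations; the cap bounds the Picard loop when a few plasma-skimming
#'   cut-off branches keep toggling (see the methods vignette).
#' @param relax_DH under-relaxation applied to diameter and hematocrit
#'   updates between outer iterations.
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(omega_net = 1.5, omega_grid = 1.94, tol = 1e-10,
                            max_sweeps = 1e5, outer_tol_P = 1e-6,
                            outer_tol_DH = 1e-4, max_outer = 120,
                            relax_DH = 0.5) {
  stopifnot(omega_net > 0, omega_net < 2, omega_grid > 0, omega_grid < 2,
            tol > 0, max_sweeps >= 1, max_outer >= 1,
            relax_DH > 0, relax_DH <= 1)
  structure(list(omega_net = omega_net, omega_grid = omega_grid, tol = tol,
                 max_sweeps = as.integer(max_sweeps),
                 outer_tol_P = outer_tol_P, outer_tol_DH = outer_tol_DH,
                 max_outer = as.integer(max_outer), relax_DH = relax_DH),
            class = "solver_settings")
}

#' Full simulation configuration
#'
#' Bundles every parameter block of the coupled model with the boundary
#' pressures of the parent vessel and the approach selector.
#'
#' @param approach solution approach: 1 (uniform-source baseline, no
#'   network), 2 (rigid vessels, constant hematocrit), or 3 (adaptive
#'   diameters, phase separation, non-Newtonian viscosity).
#' @param n_sprouts number of initial endothelial sprouts on the parent
#'   vessel (the reproduction runs use 5 or 10).
#' @param seed RNG seed for the angiogenesis generator.
#' @param P_inlet,P_outlet Dirichlet pressures at the parent-vessel inlet
#'   and outlet nodes, Pa (25 and 10 mmHg).
#' @param Pb_uniform constant intravascular pressure of the no-network
#'   baseline, Pa.
#' @param Pi_dirichlet interstitial pressure imposed on the left edge of
#'   the domain, Pa.
#' @param D_capillary initial capillary diameter, m.
#' @param D_parent parent-vessel diameter, m (held constant).
#' @param domain,tissue,angio,visc,phase,adapt,solver parameter blocks; see
#'   the respective constructors.
#' @param phase_separation logical; apply plasma skimming in approach 3.
#' @param adaptation logical; apply diameter remodeling in approach 3.
#' @param source_area exchange-area closure of the coupled approaches:
#'   `"vessel"` (default) uses the actual vessel wall area `pi D L` in
#'   each grid cell, so remodeled diameters feed back on the Starling
#'   source; `"table"` uses the tabulated per-region S/V of the
#'   homogenized tissue. Approach 1 always uses the tabulated S/V.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(approach = 3, n_sprouts = 5, seed = 1,
                              source_area = c("vessel", "table"),
                              P_inlet = 3325, P_outlet = 1330,
                              Pb_uniform = 1330, Pi_dirichlet = 0,
                              D_capillary = 12e-6, D_parent = 28e-6,
                              domain = tissue_domain(),
                              tissue = tissue_properties(),
                              angio = angio_params(n_sprouts = n_sprouts,
                                                   seed = seed),
                              visc = viscosity_law(),
                              phase = phase_sep_params(),
                              adapt = adaptation_params(),
                              solver = solver_settings(),
                              phase_separation = TRUE,
                              adaptation = TRUE) {
  source_area <- match.arg(source_area)
  stopifnot(approach %in% 1:3, P_inlet > P_outlet,
            D_capillary > 0, D_parent > 0)
  structure(list(approach = approach, n_sprouts = n_sprouts, seed = seed,
                 source_area = source_area,
                 P_inlet = P_inlet, P_outlet = P_outlet,
                 Pb_uniform = Pb_uniform, Pi_dirichlet = Pi_dirichlet,
                 D_capillary = D_capillary, D_parent = D_parent,
                 domain = domain, tissue = tissue, angio = angio,
                 visc = visc, phase = phase, adapt = adapt, solver = solver,
                 phase_separation = isTRUE(phase_separation),
                 adaptation = isTRUE(adaptation)),
            class = "simulation_config")
}
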