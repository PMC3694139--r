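#' Shear-stress set point derived from intravascular pressure
#'
#' Empirical sigmoid relating the expected wall shear stress to local
#' intravascular pressure (rat mesentery data):
#' `tau_e = 100 - 86 exp(-5000 (log10(log10 P))^5.4)` in dyn/cm^2 with P
#' in mmHg, converted here to Pa (factor 0.1). The curve is not applicable
#' below 10 mmHg, where the floor value 1.4 Pa is used; this coincides
#' with the continuous form at exactly 10 mmHg, which fixes the unit
#' convention. The set point saturates toward 10 Pa at high pressure.
#'
#' @param P_Pa intravascular pressure, Pa (vectorized).
#' @return expected wall shear stress, Pa.
#' @export
tau_e <- function(P_Pa) {
  P <- Pa_to_mmHg(P_Pa)
  out <- rep(1.4, length(P))
  hi <- P > 10
  if (any(hi)) {
    out[hi] <- 0.1 * (100 - 86 * exp(-5000 * (log10(log10(P[hi])))^5.4))
  }
  out
}

#' Remodeling stimuli of a segment
#'
#' Computes the wall-shear, pressure and metabolic contributions to the
#' total adaptation signal:
#' `S_wss = log10(s tau_w + tau_ref)`,
#' `S_p = -k_p log10(tau_e(Pb))`,
#' `S_m = k_m log10(Q_ref / (Q H) + 1)`,
#' `S_tot = S_wss + S_p + S_m - k_s`.
#' Each stimulus is evaluated in the unit its constant was calibrated in:
#' the wall-shear term with `s = stress_scale` converting tau_w from Pa
#' to dyn/cm2 (the unit of the `tau_ref = 0.103` offset; see
#' [adaptation_params()]), and the pressure term with the shear set point
#' `tau_e` in Pa (its sigmoid spans 1.4-10 Pa). Stagnant segments
#' (`Q H < Qh_floor_frac * Q_ref`) have the metabolic term evaluated at
#' the floor flux to keep it bounded.
#'
#' @param tau_w wall shear stress, Pa.
#' @param Pb_bar segment-mean intravascular pressure, Pa.
#' @param Q segment flow, m^3/s.
#' @param H segment hematocrit.
#' @param params an `adaptation_params`; `Q_ref` must be resolved (finite).
#' @return list of vectors `S_wss`, `S_p`, `S_m`, `S_tot`, `tau_e`.
#' @export
stimuli <- function(tau_w, Pb_bar, Q, H, params = adaptation_params()) {
  Q_ref <- params$Q_ref
  if (!is.finite(Q_ref) || Q_ref <= 0) {
    stop("Q_ref must be a positive finite reference flow")
  }
  te <- tau_e(Pb_bar)
  sc <- params$stress_scale
  S_wss <- log10(sc * abs(tau_w) + params$tau_ref)
  S_p <- -params$k_p * log10(te)
  qh <- pmax(abs(Q) * H, params$Qh_floor_frac * Q_ref)
  S_m <- params$k_m * log10(Q_ref / qh + 1)
  S_tot <- S_wss + S_p + S_m - params$k_s
  list(S_wss = S_wss, S_p = S_p, S_m = S_m, S_tot = S_tot, tau_e = te)
}

#' One structural adaptation step
#'
#' Applies `dD = D * dt * S_tot` to every capillary segment, clamps the
#' result to the allowed range and leaves parent segments untouched.
#'
#' @param net a solved `vessel_network` (flows, shear and hematocrit
#'   current).
#' @param params an `adaptation_params`. If `Q_ref` is `NA` the largest
#'   absolute segment flow in the network is used.
#' @param relax optional scaling (under-relaxation) of the step.
#' @return the network with updated diameters; attribute `max_rel_dD`
#'   holds max |dD| / D before clamping, attribute `stimuli` the stimulus
#'   breakdown.
#' @export
update_diameters <- function(net, params = adaptation_params(), relax = 1) {
  segs <- net$segments
  if (anyNA(segs$Q) || anyNA(segs$tau_w)) {
    stop("solve the network before adapting diameters")
  }
  if (!is.finite(params$Q_ref)) params$Q_ref <- max(abs(segs$Q))
  fi <- match(segs$from, net$nodes$id)
  ti <- match(segs$to, net$nodes$id)
  Pb_bar <- (net$nodes$pressure[fi] + net$nodes$pressure[ti]) / 2
  st <- stimuli(segs$tau_w, Pb_bar, segs$Q, segs$H, params)
  dD <- segs$D * params$dt * st$S_tot * relax
  cap <- !segs$is_parent
  Dnew <- segs$D
  Dnew[cap] <- pmin(pmax(segs$D[cap] + dD[cap], params$D_bounds[1]),
                    params$D_bounds[2])
  net$segments$D <- Dnew
  attr(net, "max_rel_dD") <- if (any(cap)) {
    max(abs(Dnew[cap] - segs$D[cap]) / segs$D[cap])
  } else 0
  attr(net, "stimuli") <- st
  net
}
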