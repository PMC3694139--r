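#' Relative apparent viscosity of blood in narrow tubes
#'
#' Empirical in-vitro law for the apparent viscosity of blood relative to
#' plasma as a function of tube diameter and discharge hematocrit. At
#' H = 0.45 it reduces to the fixed-hematocrit curve
#' `mu_45(D) = 220 exp(-1.3 D) + 3.2 - 2.44 exp(-0.06 D^0.645)` (D in um),
#' which captures the Fahraeus-Lindqvist minimum near 7 um; the hematocrit
#' dependence is shaped by the exponent
#' `C(D) = (0.8 + exp(-0.075 D)) (-1 + 1/(1 + 1e-11 D^12)) +
#'  1/(1 + 1e-11 D^12)`.
#'
#' @param D vessel diameter, m (vectorized).
#' @param H discharge hematocrit in `[0, 1)` (vectorized).
#' @param law a `viscosity_law` (only used by [apparent_viscosity()]).
#' @return dimensionless relative viscosity (`>= 1`).
#' @export
relative_viscosity <- function(D, H) {
  if (any(D <= 0)) stop("diameter must be positive")
  if (any(H < 0 | H >= 1)) stop("hematocrit must lie in [0, 1)")
  Dum <- D * 1e6
  mu45 <- 220 * exp(-1.3 * Dum) + 3.2 - 2.44 * exp(-0.06 * Dum^0.645)
  C <- visc_shape_C(Dum)
  1 + (mu45 - 1) * ((1 - H)^C - 1) / ((1 - 0.45)^C - 1)
}

visc_shape_C <- function(Dum) {
  f <- 1 / (1 + 1e-11 * Dum^12)
  (0.8 + exp(-0.075 * Dum)) * (-1 + f) + f
}

#' Apparent viscosity of blood
#'
#' `mu_app = mu_rel(D, H) * mu_plasma`.
#'
#' @inheritParams relative_viscosity
#' @return apparent viscosity, Pa s.
#' @export
apparent_viscosity <- function(D, H, law = viscosity_law()) {
  relative_viscosity(D, H) * law$mu_plasma
}

#' Hematocrit partition at a junction
#'
#' Distributes the red-cell flux entering a junction over the outgoing
#' branches. A single outlet receives the flux-weighted mixture of the
#' inlets. With several outlets the split is biased toward the faster
#' branch: relative to the slowest branch, branch j receives hematocrit in
#' the ratio `1 + zeta (U_j / U_slow - 1)`, renormalized so that red-cell
#' flux is conserved. A branch whose velocity is slower than the fastest
#' branch by more than the critical ratio `U_cr` receives no red cells at
#' all (plasma skimming cut-off). Hematocrits are clamped to
#' `[0, H_max]`; flux shed by the clamp is redistributed to the sibling
#' outlets.
#'
#' @param H_in hematocrits of the inflowing branches.
#' @param Q_in absolute volumetric flows of the inflowing branches, m^3/s.
#' @param Q_out absolute volumetric flows of the outflowing branches.
#' @param U_out mean velocities of the outflowing branches, m/s.
#' @param params a `phase_sep_params`.
#' @return hematocrit per outgoing branch, in the order of `Q_out`.
#' @export
split_hematocrit <- function(H_in, Q_in, Q_out, U_out,
                             params = phase_sep_params()) {
  if (!length(Q_out)) return(numeric())
  if (!length(Q_in)) stop("interior junction with outflow but no inflow")
  flux <- sum(H_in * Q_in)  # red-cell flux to distribute
  if (length(Q_out) == 1L) {
    return(min(flux / Q_out, params$H_max))
  }
  w <- 1 + params$zeta * (U_out / min(U_out) - 1)  # asymmetry weights
  w[U_out * params$U_cr < max(U_out)] <- 0         # cut-off branches
  if (all(w == 0)) w[which.max(U_out)] <- 1
  # conserve flux: sum(H_j * Q_j) = flux with H_j = s * w_j
  H <- w * flux / sum(w * Q_out)
  # clamp and push the excess to unclamped siblings
  for (k in seq_along(H)) {
    over <- H > params$H_max
    if (!any(over)) break
    excess <- sum((H[over] - params$H_max) * Q_out[over])
    H[over] <- params$H_max
    free <- !over & w > 0
    if (!any(free)) break
    H[free] <- H[free] + excess / sum(Q_out[free])
  }
  pmin(H, params$H_max)
}

#' Propagate hematocrit through a solved network
#'
#' Assigns segment hematocrits junction by junction in the direction of
#' flow, starting from the parent vessel which is held at `H_parent`.
#' Junctions are visited in order of decreasing nodal pressure (upstream
#' first). Because Poiseuille flow always descends nodal pressure, the
#' flow-oriented graph is acyclic and a single ordered sweep is exact; the
#' sweep is nevertheless iterated to a fixed point so that tie-degenerate
#' flow patterns (exactly equal pressures) also settle, with optional
#' under-relaxation between sweeps.
#'
#' @param net a `vessel_network` with converged flows and nodal pressures.
#' @param params a `phase_sep_params`.
#' @param relax under-relaxation factor between sweeps (1 = plain sweep,
#'   which converges in two sweeps on pressure-ordered flow).
#' @param tol convergence tolerance on max |dH|.
#' @param max_iter sweep cap.
#' @return the network with updated segment hematocrits; attribute
#'   `iterations` records the number of sweeps.
#' @export
update_network_hematocrit <- function(net, params = phase_sep_params(),
                                      relax = 1, tol = 1e-6,
                                      max_iter = 200) {
  segs <- net$segments
  nodes <- net$nodes
  if (anyNA(segs$Q)) stop("flows absent: solve the network first")
  n_seg <- nrow(segs)
  from_i <- match(segs$from, nodes$id)
  to_i <- match(segs$to, nodes$id)
  # flow-oriented endpoints: upstream node, downstream node per segment
  up_i <- ifelse(segs$Q >= 0, from_i, to_i)
  dn_i <- ifelse(segs$Q >= 0, to_i, from_i)
  U <- abs(segs$Q) / (pi * segs$D^2 / 4)
  parent_touch <- segs$is_parent
  # nodes on the parent vessel feed the network at H_parent
  parent_nodes <- unique(c(from_i[parent_touch], to_i[parent_touch]))
  H <- ifelse(parent_touch, params$H_parent, segs$H)
  H[is.na(H)] <- params$H_parent
  ord <- order(-nodes$pressure)
  zero_flow <- abs(segs$Q) <= 0
  n_nodes <- nrow(nodes)
  is_parent_node <- rep(FALSE, n_nodes)
  is_parent_node[parent_nodes] <- TRUE
  live <- which(!zero_flow)
  out_of <- vector("list", n_nodes)
  in_of <- vector("list", n_nodes)
  sp <- split(live, up_i[live])
  out_of[as.integer(names(sp))] <- sp
  sp <- split(live, dn_i[live])
  in_of[as.integer(names(sp))] <- sp
  absQ <- abs(segs$Q)
  it <- 0L
  repeat {
    it <- it + 1L
    H_old <- H
    for (ni in ord) {
      if (is_parent_node[ni]) next
      outs <- out_of[[ni]]
      if (is.null(outs)) next
      ins <- in_of[[ni]]
      if (is.null(ins)) next
      Hnew <- split_hematocrit(H[ins], absQ[ins], absQ[outs], U[outs],
                               params)
      H[outs] <- Hnew
    }
    H[parent_touch] <- params$H_parent
    delta <- max(abs(H - H_old))
    if (delta < tol || it >= max_iter) break
    H <- H_old + relax * (H - H_old)
    H[parent_touch] <- params$H_parent
  }
  if (it >= max_iter && delta >= tol) {
    warning(sprintf("hematocrit iteration stopped at max_iter with dH = %.3g",
                    delta))
  }
  net$segments$H <- H
  attr(net, "iterations") <- it
  net
}
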