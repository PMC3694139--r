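#' Poiseuille flow through a cylindrical segment
#'
#' `Q = pi D^4 dP / (128 mu L)`, signed with the pressure drop.
#'
#' @param D diameter, m.
#' @param L length, m.
#' @param dP driving pressure difference, Pa.
#' @param mu_app apparent viscosity, Pa s.
#' @return volumetric flow, m^3/s.
#' @export
poiseuille_flow <- function(D, L, dP, mu_app) {
  if (any(D <= 0) || any(L <= 0) || any(mu_app <= 0)) {
    stop("diameter, length and viscosity must be positive")
  }
  pi * D^4 * dP / (128 * mu_app * L)
}

#' Starling transvascular flow of a segment
#'
#' Filtration across the segment wall driven by the transmural hydrostatic
#' difference minus the reflection-weighted oncotic difference, using the
#' segment-averaged intravascular and interstitial pressures:
#' `Qt = Lp (pi D L) ((Pb - Pi) - sigma (pi_B - pi_i))`.
#' Positive values are filtration out of the vessel.
#'
#' @param D,L segment diameter and length, m.
#' @param Pb_bar mean of the endpoint nodal blood pressures, Pa.
#' @param Pi_bar mean interstitial pressure at the segment's cells, Pa.
#' @param Lp wall hydraulic conductivity, m/(Pa s).
#' @param sigma_dpi reflection-weighted oncotic jump
#'   `sigma * (pi_B - pi_i)`, Pa.
#' @return transvascular flow, m^3/s.
#' @export
starling_flow <- function(D, L, Pb_bar, Pi_bar, Lp, sigma_dpi) {
  Lp * (pi * D * L) * ((Pb_bar - Pi_bar) - sigma_dpi)
}

#' Wall shear stress of a segment
#'
#' `tau_w = 32 mu |Q| / (pi D^3)`.
#'
#' @param D diameter, m.
#' @param Q volumetric flow, m^3/s.
#' @param mu_app apparent viscosity, Pa s.
#' @return wall shear stress, Pa.
#' @export
wall_shear <- function(D, Q, mu_app) {
  32 * mu_app * abs(Q) / (pi * D^3)
}

# Sparse symmetric solve of the nodal balance system. Interior node c:
# sum_s [g_s (P_k - P_c) - 0.5 lambda_s ((P_c + P_k)/2 - Pe_s)] = 0;
# Dirichlet nodes are identity rows.
nodal_direct_solve <- function(n, fi, ti, g, lambda, Pe, dirichlet, P0) {
  # scale conductances to O(1) so the balance rows and the unit Dirichlet
  # rows share a pivot scale
  s0 <- max(g + lambda / 4)
  g <- g / s0
  lambda <- lambda / s0
  off <- g - lambda / 4
  dia <- g + lambda / 4
  rhs_seg <- lambda / 2 * Pe
  ii <- c(fi, ti, fi, ti)
  jj <- c(ti, fi, fi, ti)
  xx <- c(-off, -off, dia, dia)
  rhs <- numeric(n)
  acc <- tapply(c(rhs_seg, rhs_seg), c(fi, ti), sum)
  rhs[as.integer(names(acc))] <- as.numeric(acc)
  # overwrite Dirichlet rows with identity; move their columns to the rhs
  keep <- !(dirichlet[ii])
  movers <- keep & dirichlet[jj]
  if (any(movers)) {
    mv <- tapply(-xx[movers] * P0[jj[movers]], ii[movers], sum)
    rhs[as.integer(names(mv))] <- rhs[as.integer(names(mv))] + as.numeric(mv)
  }
  keep <- keep & !dirichlet[jj]
  iso <- setdiff(seq_len(n), unique(c(fi, ti)))  # degree-0 nodes
  fixed <- which(dirichlet)
  A <- Matrix::sparseMatrix(
    i = c(ii[keep], fixed, iso), j = c(jj[keep], fixed, iso),
    x = c(xx[keep], rep(1, length(fixed) + length(iso))),
    dims = c(n, n))
  rhs[fixed] <- P0[fixed]
  rhs[iso] <- P0[iso]
  as.numeric(Matrix::solve(A, rhs))
}

nodal_residual <- function(n, fi, ti, g, lambda, Pe, P) {
  contrib <- function(a, b) {
    g * (P[b] - P[a]) - 0.5 * lambda * (0.5 * (P[a] + P[b]) - Pe)
  }
  r <- numeric(n)
  acc <- tapply(c(contrib(fi, ti), contrib(ti, fi)), c(fi, ti), sum)
  r[as.integer(names(acc))] <- as.numeric(acc)
  r
}

# Per-segment wall coefficients (Lp, sigma_dpi) by midpoint region, and
# per-segment mean interstitial pressure sampled at the endpoint cells.
segment_wall_coeffs <- function(net, domain, tissue) {
  segs <- net$segments
  fi <- match(segs$from, net$nodes$id)
  ti <- match(segs$to, net$nodes$id)
  xm <- (net$nodes$x[fi] + net$nodes$x[ti]) / 2
  ym <- (net$nodes$y[fi] + net$nodes$y[ti]) / 2
  region <- point_region(domain, xm, ym)
  list(Lp = tissue$Lp[region], sigma_dpi = tissue$sigma_dpi[region],
       region = region)
}

segment_interstitial_pressure <- function(net, domain, Pi) {
  segs <- net$segments
  fi <- match(segs$from, net$nodes$id)
  ti <- match(segs$to, net$nodes$id)
  cell_of <- function(idx) {
    i <- pmin(pmax(ceiling(net$nodes$x[idx] / domain$h), 1L), domain$nx)
    j <- pmin(pmax(ceiling(net$nodes$y[idx] / domain$h), 1L), domain$ny)
    cbind(i, j)
  }
  (Pi[cell_of(fi)] + Pi[cell_of(ti)]) / 2
}

#' Solve nodal blood pressures in a network
#'
#' Imposes mass conservation at every interior node: the Poiseuille flows
#' of the incident segments balance the transvascular (Starling) losses,
#' each segment's loss being shared half-and-half between its endpoints.
#' Inlet and outlet nodes carry fixed Dirichlet pressures. The linear
#' system is solved by successive over-relaxation; viscosities and
#' hematocrits are taken as frozen (Picard linearization).
#'
#' @param net a `vessel_network` with segment viscosities `mu` set.
#' @param domain a `tissue_domain`.
#' @param tissue a `tissue_properties`.
#' @param Pi interstitial pressure: a matrix over the grid, or a single
#'   number used for every segment.
#' @param P_inlet,P_outlet Dirichlet pressures, Pa.
#' @param settings a `solver_settings`.
#' @param leakage logical; set `FALSE` to solve the sealed network
#'   (`Lp = 0`).
#' @param method `"direct"` (default) solves the sparse symmetric
#'   positive-definite system exactly; `"sor"` runs the
#'   successive-over-relaxation sweep of the published algorithm. The two
#'   agree to solver tolerance; the direct route is the default because
#'   the pruned lattice networks are long chains whose SOR spectral
#'   radius approaches one.
#' @return the network with nodal `pressure`, segment `Q`, `Qt`, `tau_w`
#'   filled in; attributes `sweeps`, `residual` (per node) and `U`
#'   (per-segment mean velocity, m/s).
#' @export
solve_nodal_pressures <- function(net, domain, tissue, Pi = 0,
                                  P_inlet = 3325, P_outlet = 1330,
                                  settings = solver_settings(),
                                  leakage = TRUE,
                                  method = c("direct", "sor")) {
  method <- match.arg(method)
  nodes <- net$nodes
  segs <- net$segments
  if (!nrow(segs)) stop("network has no segments")
  if (anyNA(segs$mu)) stop("segment viscosities must be set before solving")
  n <- nrow(nodes)
  fi <- match(segs$from, nodes$id)
  ti <- match(segs$to, nodes$id)
  g <- pi * segs$D^4 / (128 * segs$mu * segs$L)
  wc <- segment_wall_coeffs(net, domain, tissue)
  lambda <- if (leakage) wc$Lp * pi * segs$D * segs$L else rep(0, nrow(segs))
  Pi_bar <- if (is.matrix(Pi)) {
    segment_interstitial_pressure(net, domain, Pi)
  } else {
    rep(Pi, nrow(segs))
  }
  Pe <- Pi_bar + wc$sigma_dpi
  dirichlet <- nodes$role %in% c("inlet", "outlet")
  P0 <- nodes$pressure
  P0[is.na(P0)] <- P_outlet
  P0[nodes$role == "inlet"] <- P_inlet
  P0[nodes$role == "outlet"] <- P_outlet
  if (method == "direct") {
    P <- nodal_direct_solve(n, fi, ti, g, lambda, Pe, dirichlet, P0)
    sweeps <- 1L
    residual <- nodal_residual(n, fi, ti, g, lambda, Pe, P)
  } else {
    # CSR adjacency over both segment directions
    ends <- c(fi, ti)
    far <- c(ti, fi)
    sid <- rep(seq_len(nrow(segs)), 2L)
    o <- order(ends)
    ptr <- c(0L, cumsum(tabulate(ends, nbins = n)))
    sol <- sor_network_cpp(ptr, far[o] - 1L, sid[o] - 1L, g, lambda, Pe, P0,
                           dirichlet, settings$omega_net, settings$tol,
                           settings$max_sweeps)
    if (sol$delta / max(abs(sol$P), 1e-300) >= settings$tol) {
      stop(sprintf("nodal SOR did not converge in %d sweeps (delta = %.3g)",
                   settings$max_sweeps, sol$delta))
    }
    P <- sol$P
    sweeps <- sol$sweeps
    residual <- sol$residual
  }
  net$nodes$pressure <- P
  net$segments$Q <- g * (P[fi] - P[ti])
  net$segments$Qt <- lambda * ((P[fi] + P[ti]) / 2 - Pe)
  net$segments$tau_w <- wall_shear(segs$D, net$segments$Q, segs$mu)
  attr(net, "sweeps") <- sweeps
  attr(net, "residual") <- residual
  attr(net, "U") <- abs(net$segments$Q) / (pi * segs$D^2 / 4)
  net
}

#' Global mass balance of a solved network
#'
#' The flow delivered by the inlet equals the flow recovered at the outlet
#' plus the total transvascular leakage. Each segment's leakage is shared
#' half-and-half between its endpoint nodes in the nodal balance, so the
#' shares allocated to the inlet/outlet nodes belong to the boundary
#' flows.
#'
#' @param net a solved `vessel_network`.
#' @return list with `inflow` (flow entering the network at the inlet,
#'   including the inlet's leak share), `outflow` (flow leaving at the
#'   outlet net of its leak share), `leak` (sum of transvascular flows)
#'   and `relative_residual` `|inflow - outflow - leak| / inflow`.
#' @export
mass_balance <- function(net) {
  nodes <- net$nodes
  segs <- net$segments
  node_net <- function(id) {
    out_s <- segs$from == id
    in_s <- segs$to == id
    sum(segs$Q[out_s]) - sum(segs$Q[in_s]) +
      0.5 * sum(segs$Qt[out_s | in_s])
  }
  inlet <- nodes$id[nodes$role == "inlet"]
  outlet <- nodes$id[nodes$role == "outlet"]
  inflow <- sum(vapply(inlet, node_net, numeric(1)))
  outflow <- -sum(vapply(outlet, node_net, numeric(1)))
  leak <- sum(segs$Qt)
  list(inflow = inflow, outflow = outflow, leak = leak,
       relative_residual = abs(inflow - outflow - leak) /
         max(abs(inflow), 1e-300))
}
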