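#' Starling source rate of a tissue cell
#'
#' Rate of fluid gain per unit tissue volume from the vasculature:
#' `Phi_B = A Lp (S/V) ((Pb - Pi) - sigma (pi_B - pi_i))`, 1/s. Cells
#' without a capillary (`A = 0`) have no source. Lymphatic drainage is
#' neglected (`Phi_L = 0`).
#'
#' @param Pi interstitial pressure, Pa.
#' @param Pb intravascular pressure assigned to the cell, Pa.
#' @param Lp wall hydraulic conductivity, m/(Pa s).
#' @param SV exchange area per unit volume, 1/m.
#' @param sigma_dpi reflection-weighted oncotic jump, Pa.
#' @param A capillary indicator (0/1).
#' @return source rate, 1/s (vectorized).
#' @export
source_term <- function(Pi, Pb, Lp, SV, sigma_dpi, A = 1) {
  A * Lp * SV * ((Pb - Pi) - sigma_dpi)
}

# Per-cell coefficient fields over the domain.
grid_coefficients <- function(domain, tissue) {
  reg <- ifelse(domain$tumor_mask, "tumor", "normal")
  list(K = matrix(tissue$K[reg], domain$nx, domain$ny),
       LpSV = matrix(tissue$Lp[reg] * tissue$SV[reg], domain$nx, domain$ny),
       sigma_dpi = matrix(tissue$sigma_dpi[reg], domain$nx, domain$ny))
}

#' Solve the interstitial pressure field
#'
#' Finite-difference solution of the Darcy continuity equation
#' `-div(K grad Pi) = Phi_B(Pi)` on the cell-centered grid, with the
#' Starling source linearized in `Pi` (it only adds a positive diagonal
#' term, so the sweep is unconditionally stable). The left edge carries a
#' Dirichlet condition; the other three edges are no-flux. Hydraulic
#' conductivity is harmonically averaged at cell faces so the scheme is
#' conservative across the tumor boundary.
#'
#' @param domain a `tissue_domain`.
#' @param tissue a `tissue_properties`.
#' @param A capillary indicator matrix (0/1), nx by ny.
#' @param Pb per-cell intravascular pressure, matrix or single number.
#' @param Pi_dirichlet pressure imposed on the left edge, Pa.
#' @param settings a `solver_settings`.
#' @param P0 optional warm-start field.
#' @param SV optional per-cell exchange surface density matrix (m^2 of
#'   vessel wall per m^3 of tissue, as produced by
#'   [map_segments_to_grid()]). When given it replaces the tabulated
#'   per-region S/V in the source coefficient, so that the exchange area
#'   follows the actual (possibly remodeled) vessels in each cell; the
#'   tabulated S/V describes the homogenized no-network tissue.
#' @return object of class `interstitial_field`: list with `P` (Pa,
#'   nx by ny), `Phi_B` (1/s), `sweeps`, and the inputs needed by
#'   [darcy_velocity()].
#' @export
solve_interstitial_pressure <- function(domain, tissue, A, Pb,
                                        Pi_dirichlet = 0,
                                        settings = solver_settings(),
                                        P0 = NULL, SV = NULL) {
  nx <- domain$nx; ny <- domain$ny; h <- domain$h
  co <- grid_coefficients(domain, tissue)
  if (!is.matrix(Pb)) Pb <- matrix(Pb, nx, ny)
  if (!is.matrix(A)) A <- matrix(A, nx, ny)
  # harmonic face transmissibilities K_face / h^2
  Tx <- matrix(0, nx + 1, ny)
  Kh <- co$K
  Tx[2:nx, ] <- 2 * Kh[-nx, ] * Kh[-1, ] / (Kh[-nx, ] + Kh[-1, ]) / h^2
  Ty <- matrix(0, nx, ny + 1)
  Ty[, 2:ny] <- 2 * Kh[, -ny] * Kh[, -1] / (Kh[, -ny] + Kh[, -1]) / h^2
  TxBnd <- 2 * Kh[1, ] / h^2          # Dirichlet half-cell, left edge
  PxBnd <- rep(Pi_dirichlet, ny)
  alpha <- if (is.null(SV)) {
    A * co$LpSV
  } else {
    reg <- ifelse(domain$tumor_mask, "tumor", "normal")
    A * matrix(tissue$Lp[reg], nx, ny) * SV
  }
  Pe <- Pb - co$sigma_dpi
  if (is.null(P0)) P0 <- matrix(Pi_dirichlet, nx, ny)
  sol <- sor_grid_cpp(nx, ny, as.numeric(Tx), as.numeric(Ty), TxBnd, PxBnd,
                      as.numeric(alpha), as.numeric(Pe), as.numeric(P0),
                      settings$omega_grid, settings$tol, settings$max_sweeps)
  if (sol$delta / max(abs(sol$P), 1e-300) >= settings$tol) {
    stop(sprintf("interstitial SOR did not converge in %d sweeps (delta = %.3g)",
                 settings$max_sweeps, sol$delta))
  }
  P <- matrix(sol$P, nx, ny)
  structure(list(P = P, Phi_B = alpha * (Pe - P), A = A,
                 K = co$K, domain = domain, sweeps = sol$sweeps),
            class = "interstitial_field")
}

#' @export
print.interstitial_field <- function(x, ...) {
  cat(sprintf("interstitial_field: %d x %d, max P_i = %.4g Pa (%d SOR sweeps)\n",
              nrow(x$P), ncol(x$P), max(x$P), x$sweeps))
  invisible(x)
}

#' Darcy velocity of an interstitial field
#'
#' `v = -K grad Pi` evaluated at interior cell faces with harmonically
#' averaged conductivity.
#'
#' @param field an `interstitial_field`.
#' @return list with `vx` ((nx-1) by ny, on vertical interior faces),
#'   `vy` (nx by (ny-1)), and `speed` (cell-centered magnitude, nx by ny),
#'   all in m/s.
#' @export
darcy_velocity <- function(field) {
  P <- field$P; K <- field$K
  h <- field$domain$h
  nx <- nrow(P); ny <- ncol(P)
  Kx <- 2 * K[-nx, ] * K[-1, ] / (K[-nx, ] + K[-1, ])
  Ky <- 2 * K[, -ny] * K[, -1] / (K[, -ny] + K[, -1])
  vx <- -Kx * (P[-1, ] - P[-nx, ]) / h
  vy <- -Ky * (P[, -1] - P[, -ny]) / h
  cx <- (rbind(vx, 0) + rbind(0, vx)) / 2
  cy <- (cbind(vy, 0) + cbind(0, vy)) / 2
  list(vx = vx, vy = vy, speed = sqrt(cx^2 + cy^2))
}

#' Export a field as plain text or legacy VTK
#'
#' @param M matrix to export (nx by ny, x varies along rows).
#' @param file output path.
#' @param h grid spacing, m (VTK only).
#' @param name scalar name (VTK only).
#' @return the path, invisibly.
#' @export
write_field_matrix <- function(M, file) {
  write.table(t(M), file, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_field_matrix
#' @export
write_field_vtk <- function(M, file, h = 1, name = "pressure") {
  nx <- nrow(M); ny <- ncol(M)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %g %g 0", h / 2, h / 2),
               sprintf("SPACING %g %g 1", h, h),
               sprintf("POINT_DATA %d", nx * ny),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(M), digits = 9), con)
  invisible(file)
}
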