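#' Tissue domain: 2-D grid with tumor mask
#'
#' Square tissue domain discretized into `nx` by `ny` cells with uniform
#' spacing. The tumor is a disc centered on the midpoint of the right edge
#' (only its half inside the square belongs to the domain); the parent
#' vessel runs along the left edge. Network nodes live at cell centers, so
#' lattice segments have length equal to the cell size `h`.
#'
#' @param nx,ny grid cells per side.
#' @param length_m domain side length, m.
#' @param tumor_radius radius of the tumor disc, m.
#' @param tumor_center optional (x, y) of the tumor center, m; default is
#'   the midpoint of the right edge.
#' @return object of class `tissue_domain`: list with `nx`, `ny`, `h`,
#'   `length`, cell-center coordinate vectors `xc`, `yc`, and logical
#'   matrix `tumor_mask` (`nx` rows indexed by x, `ny` columns by y).
#' @export
tissue_domain <- function(nx = 100, ny = 100, length_m = 2e-3,
                          tumor_radius = 0.2e-3, tumor_center = NULL) {
  stopifnot(nx >= 3, ny >= 3, length_m > 0, tumor_radius >= 0)
  h <- length_m / nx
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h * (ny / ny)  # uniform square cells
  if (is.null(tumor_center)) tumor_center <- c(length_m, length_m / 2)
  dx <- outer(xc - tumor_center[1], rep(1, ny))
  dy <- outer(rep(1, nx), yc - tumor_center[2])
  mask <- (dx * dx + dy * dy) <= tumor_radius^2
  structure(list(nx = as.integer(nx), ny = as.integer(ny), h = h,
                 length = length_m, xc = xc, yc = yc,
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 tumor_mask = mask),
            class = "tissue_domain")
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat(sprintf("tissue_domain: %d x %d cells, %.3g mm square, h = %.3g um\n",
              x$nx, x$ny, x$length * 1e3, x$h * 1e6))
  cat(sprintf("  tumor disc: radius %.3g mm at (%.3g, %.3g) mm; %d tumor cells\n",
              x$tumor_radius * 1e3, x$tumor_center[1] * 1e3,
              x$tumor_center[2] * 1e3, sum(x$tumor_mask)))
  invisible(x)
}

# Region label ("normal"/"tumor") of the cell containing point (x, y).
point_region <- function(domain, x, y) {
  i <- pmin(pmax(ceiling(x / domain$h), 1L), domain$nx)
  j <- pmin(pmax(ceiling(y / domain$h), 1L), domain$ny)
  ifelse(domain$tumor_mask[cbind(i, j)], "tumor", "normal")
}
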