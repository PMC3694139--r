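#' Capillary network graph
#'
#' A vessel network is a pair of data frames: `nodes` with columns
#' `id`, `x`, `y` (m), `role` (one of `"interior"`, `"inlet"`, `"outlet"`)
#' and `pressure` (Pa), and `segments` with columns `id`, `from`, `to`
#' (node ids), `D` (m), `L` (m), `H` (discharge hematocrit), `mu`
#' (apparent viscosity, Pa s), `Q` (signed flow from `from` to `to`,
#' m^3/s), `Qt` (transvascular flow, positive out of the vessel, m^3/s),
#' `tau_w` (wall shear stress, Pa) and `is_parent` (logical).
#'
#' @param nodes node data frame (at least `id`, `x`, `y`; missing `role`
#'   defaults to `"interior"`, missing `pressure` to `NA`).
#' @param segments segment data frame (at least `from`, `to`).
#' @return object of class `vessel_network`.
#' @export
vessel_network <- function(nodes, segments) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (!"role" %in% names(nodes)) nodes$role <- "interior"
  if (!"pressure" %in% names(nodes)) nodes$pressure <- NA_real_
  bad <- !(segments$from %in% nodes$id & segments$to %in% nodes$id)
  if (any(bad)) {
    stop(sprintf("dangling edge reference in %d segment(s)", sum(bad)))
  }
  if (nrow(segments)) {
    if (!"id" %in% names(segments)) segments$id <- seq_len(nrow(segments))
    key <- paste(pmin(segments$from, segments$to),
                 pmax(segments$from, segments$to))
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    if (any(segments$from == segments$to)) stop("self-loop edge")
  } else {
    segments <- empty_segments()
  }
  structure(list(nodes = nodes, segments = segments),
            class = "vessel_network")
}

empty_segments <- function() {
  data.frame(id = integer(), from = integer(), to = integer(),
             D = numeric(), L = numeric(), H = numeric(), mu = numeric(),
             Q = numeric(), Qt = numeric(), tau_w = numeric(),
             is_parent = logical())
}

#' Build a vessel network from node and edge tables
#'
#' Applies capillary defaults to edges that do not state them: diameter
#' 12 um for capillaries (28 um for parent segments), hematocrit 0.45,
#' segment length from the endpoint geometry.
#'
#' @param nodes data frame with `id`, `x`, `y` and optional `role`.
#' @param edges data frame with `from`, `to` and optional `D`, `L`, `H`,
#'   `is_parent`.
#' @param D_capillary default capillary diameter, m.
#' @param D_parent default parent-vessel diameter, m.
#' @param H_default default discharge hematocrit.
#' @return a `vessel_network`.
#' @export
build_network <- function(nodes, edges, D_capillary = 12e-6,
                          D_parent = 28e-6, H_default = 0.45) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (!"is_parent" %in% names(edges)) edges$is_parent <- FALSE
  idx <- match(edges$from, nodes$id)
  jdx <- match(edges$to, nodes$id)
  if (anyNA(idx) || anyNA(jdx)) stop("dangling edge reference")
  len <- sqrt((nodes$x[idx] - nodes$x[jdx])^2 +
              (nodes$y[idx] - nodes$y[jdx])^2)
  if (!"L" %in% names(edges)) edges$L <- len
  edges$L[is.na(edges$L)] <- len[is.na(edges$L)]
  if (any(edges$L <= 0)) stop("zero-length edge")
  if (!"D" %in% names(edges)) edges$D <- NA_real_
  edges$D[is.na(edges$D)] <- ifelse(edges$is_parent[is.na(edges$D)],
                                    D_parent, D_capillary)
  if (!"H" %in% names(edges)) edges$H <- H_default
  edges$H[is.na(edges$H)] <- H_default
  if (!"mu" %in% names(edges)) edges$mu <- NA_real_
  for (col in c("Q", "Qt", "tau_w")) if (!col %in% names(edges)) {
    edges[[col]] <- NA_real_
  }
  if (!"id" %in% names(edges)) edges$id <- seq_len(nrow(edges))
  vessel_network(nodes, edges[, c("id", "from", "to", "D", "L", "H", "mu",
                                  "Q", "Qt", "tau_w", "is_parent")])
}

#' @export
print.vessel_network <- function(x, ...) {
  deg <- node_degrees(x)
  cat(sprintf("vessel_network: %d nodes, %d segments (%d parent)\n",
              nrow(x$nodes), nrow(x$segments), sum(x$segments$is_parent)))
  if (length(deg)) {
    cat(sprintf("  degree range %d-%d; D range %.3g-%.3g um\n",
                min(deg), max(deg), min(x$segments$D) * 1e6,
                max(x$segments$D) * 1e6))
  }
  invisible(x)
}

#' Node degrees
#'
#' @param net a `vessel_network`.
#' @return integer vector of incident-segment counts, one per row of
#'   `net$nodes`, in node order.
#' @export
node_degrees <- function(net) {
  ids <- net$nodes$id
  tab <- table(factor(c(net$segments$from, net$segments$to), levels = ids))
  as.integer(tab)
}

#' Remove segments that cannot belong to a perfused loop
#'
#' Repeatedly strips segments incident to interior nodes of degree less
#' than two until none remain. Inlet and outlet nodes (the parent-vessel
#' boundary attachments) are exempt. The result is idempotent and keeps
#' every segment that lies on a cycle.
#'
#' @param net a `vessel_network`.
#' @return pruned `vessel_network` with attribute `removed_segments`
#'   (ids of dropped segments). Errors if pruning removes every segment,
#'   signaling that the angiogenesis run produced no anastomosis.
#' @export
prune_topological <- function(net) {
  segs <- net$segments
  nodes <- net$nodes
  exempt <- nodes$id[nodes$role %in% c("inlet", "outlet")]
  removed <- integer()
  repeat {
    if (!nrow(segs)) break
    deg <- table(factor(c(segs$from, segs$to),
                        levels = unique(c(segs$from, segs$to))))
    weak <- as.integer(names(deg))[deg < 2]
    weak <- setdiff(weak, exempt)
    if (!length(weak)) break
    drop <- segs$from %in% weak | segs$to %in% weak
    removed <- c(removed, segs$id[drop])
    segs <- segs[!drop, , drop = FALSE]
  }
  if (!nrow(segs)) {
    stop("no perfused loop: pruning removed every segment ",
         "(the angiogenesis run produced no anastomosis)")
  }
  out <- vessel_network(nodes, segs)
  attr(out, "removed_segments") <- removed
  out
}

#' Remove low-flow segments
#'
#' Drops every segment whose absolute flow is below `fraction` of the
#' network's maximum absolute flow.
#'
#' @param net a `vessel_network` with solved flows.
#' @param fraction flow threshold as a fraction of the maximum; the
#'   conventional choice is 0.01 (1 percent).
#' @return pruned `vessel_network` with attribute `removed_segments`.
#' @export
prune_by_flow <- function(net, fraction = 0.01) {
  segs <- net$segments
  if (!nrow(segs)) return(net)
  if (anyNA(segs$Q)) stop("flows absent: solve the network before flow pruning")
  if (fraction <= 0) {
    attr(net, "removed_segments") <- integer()
    return(net)
  }
  thr <- fraction * max(abs(segs$Q))
  drop <- abs(segs$Q) < thr
  out <- vessel_network(net$nodes, segs[!drop, , drop = FALSE])
  attr(out, "removed_segments") <- segs$id[drop]
  out
}

#' Map network segments onto the tissue grid
#'
#' Marks the capillary source indicator `A` on every grid cell containing
#' at least one segment endpoint, and assigns each marked cell the
#' unweighted mean of the endpoint nodal pressures of its incident
#' segments.
#'
#' @param net a `vessel_network` whose node pressures are set (cells of
#'   unsolved networks get the mean of `NA`, i.e. `NA`).
#' @param domain a `tissue_domain`.
#' @return list with `A` (0/1 matrix, nx by ny), `Pb` (matrix of
#'   per-cell mean intravascular pressure, 0 where `A == 0`), `SV`
#'   (exchange surface density, m^2 of vessel wall per m^3 of tissue:
#'   each segment contributes half its wall area `pi D L` to each
#'   endpoint cell of volume `h^3`), and `Dbar` (mean diameter of the
#'   segments incident to each cell, m; 0 where `A == 0`).
#' @export
map_segments_to_grid <- function(net, domain) {
  A <- matrix(0L, domain$nx, domain$ny)
  Pb <- matrix(0, domain$nx, domain$ny)
  SV <- matrix(0, domain$nx, domain$ny)
  Dbar <- matrix(0, domain$nx, domain$ny)
  segs <- net$segments
  if (!nrow(segs)) return(list(A = A, Pb = Pb, SV = SV, Dbar = Dbar))
  nidx <- match(c(segs$from, segs$to), net$nodes$id)
  x <- net$nodes$x[nidx]; y <- net$nodes$y[nidx]
  eps <- 1e-9 * domain$h
  if (any(x < -eps | x > domain$length + eps |
          y < -eps | y > domain$h * domain$ny + eps)) {
    stop("segment endpoint outside the tissue domain")
  }
  ci <- pmin(pmax(ceiling(x / domain$h), 1L), domain$nx)
  cj <- pmin(pmax(ceiling(y / domain$h), 1L), domain$ny)
  # endpoint k of segment s contributes the mean of both endpoint
  # pressures of s to the cell holding endpoint k
  pfrom <- net$nodes$pressure[match(segs$from, net$nodes$id)]
  pto <- net$nodes$pressure[match(segs$to, net$nodes$id)]
  pmean <- rep((pfrom + pto) / 2, 2)
  cell <- ci + (cj - 1L) * domain$nx
  psum <- tapply(pmean, cell, sum)
  pcnt <- tapply(pmean, cell, length)
  cells <- as.integer(names(psum))
  A[cells] <- 1L
  Pb[cells] <- as.numeric(psum / pcnt)
  wall_half <- rep(pi * segs$D * segs$L / 2, 2)  # half area per endpoint
  asum <- tapply(wall_half, cell, sum)
  SV[cells] <- as.numeric(asum) / domain$h^3
  dsum <- tapply(rep(segs$D, 2), cell, sum)
  Dbar[cells] <- as.numeric(dsum / pcnt)
  list(A = A, Pb = Pb, SV = SV, Dbar = Dbar)
}

#' Write / read a network as a CSV pair
#'
#' Deterministic column order; pressures and flows are carried along so a
#' write/read round trip is lossless to at least 12 significant digits.
#'
#' @param net a `vessel_network`.
#' @param nodes_file,segments_file file paths.
#' @return `write_network_csv` returns the paths invisibly;
#'   `read_network_csv` returns a `vessel_network`.
#' @export
write_network_csv <- function(net, nodes_file, segments_file) {
  nd <- data.frame(id = net$nodes$id,
                   x_m = formatC(net$nodes$x, digits = 15, format = "g"),
                   y_m = formatC(net$nodes$y, digits = 15, format = "g"),
                   role = net$nodes$role,
                   pressure_Pa = formatC(net$nodes$pressure, digits = 15,
                                         format = "g"))
  sg <- net$segments
  sgo <- data.frame(id = sg$id, node_a = sg$from, node_b = sg$to)
  for (col in c("D", "L", "H", "mu", "Q", "Qt", "tau_w")) {
    sgo[[col]] <- formatC(sg[[col]], digits = 15, format = "g")
  }
  names(sgo)[4:10] <- c("diameter_m", "length_m", "hematocrit",
                        "viscosity_Pas", "flow_m3s", "transvascular_m3s",
                        "wall_shear_Pa")
  sgo$is_parent <- sg$is_parent
  write.csv(nd, nodes_file, row.names = FALSE, quote = FALSE)
  write.csv(sgo, segments_file, row.names = FALSE, quote = FALSE)
  invisible(c(nodes_file, segments_file))
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(nodes_file, segments_file) {
  nd <- read.csv(nodes_file, stringsAsFactors = FALSE)
  sg <- read.csv(segments_file, stringsAsFactors = FALSE)
  nodes <- data.frame(id = nd$id, x = nd$x_m, y = nd$y_m, role = nd$role,
                      pressure = nd$pressure_Pa)
  segments <- data.frame(id = sg$id, from = sg$node_a, to = sg$node_b,
                         D = sg$diameter_m, L = sg$length_m,
                         H = sg$hematocrit, mu = sg$viscosity_Pas,
                         Q = sg$flow_m3s, Qt = sg$transvascular_m3s,
                         tau_w = sg$wall_shear_Pa,
                         is_parent = as.logical(sg$is_parent))
  vessel_network(nodes, segments)
}

#' Parent vessel as a lattice chain on the left edge
#'
#' The pre-existing parent vessel is represented as a chain of
#' fixed-diameter segments along the left column of cell centers, with the
#' inlet node at the bottom end and the outlet node at the top end.
#'
#' @param domain a `tissue_domain`.
#' @param D_parent parent diameter, m.
#' @return a `vessel_network` holding only the parent chain.
#' @export
parent_vessel <- function(domain, D_parent = 28e-6) {
  ny <- domain$ny
  nodes <- data.frame(id = seq_len(ny),
                      x = rep(domain$h / 2, ny),
                      y = domain$yc,
                      role = c("inlet", rep("interior", ny - 2), "outlet"),
                      pressure = NA_real_)
  edges <- data.frame(from = seq_len(ny - 1), to = seq_len(ny - 1) + 1L,
                      is_parent = TRUE)
  build_network(nodes, edges, D_parent = D_parent)
}
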