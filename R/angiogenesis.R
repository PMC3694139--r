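#' Parameters of the discrete sprouting-angiogenesis model
#'
#' Dimensionless constants of the lattice tip-migration model: random
#' motility, saturating chemotaxis toward tumor angiogenic factor (TAF),
#' haptotaxis up the fibronectin gradient, TAF uptake by tips and
#' fibronectin production/degradation, plus the branching schedule.
#' Defaults are the conventional values of the discrete endothelial-tip
#' model this generator follows; see the methods vignette.
#'
#' @param n_sprouts number of initial sprouts on the parent vessel.
#' @param seed RNG seed.
#' @param diffusion random-motility coefficient of the tips.
#' @param chi0 chemotaxis coefficient.
#' @param chi_sat saturation constant of the chemotactic response
#'   (`chi = chi0 / (1 + chi_sat * taf)`).
#' @param rho haptotaxis coefficient.
#' @param taf_uptake TAF consumption rate by a tip occupying a cell.
#' @param fib_production,fib_degradation fibronectin kinetics at tip cells.
#' @param taf_scale,fib_scale length scales of the initial exponential
#'   TAF and fibronectin profiles (dimensionless, domain side = 1).
#' @param fib_level fibronectin level at the parent vessel.
#' @param k_step lattice time step entering the stencil coefficients.
#' @param branch_ages minimum tip age (steps) before it may branch.
#' @param branch_taf,branch_prob branching-probability schedule: a tip in
#'   a cell with TAF in `(branch_taf[i], branch_taf[i+1]]` branches with
#'   probability `branch_prob[i]`.
#' @param max_steps cap on walker steps.
#' @return object of class `angio_params`.
#' @export
angio_params <- function(n_sprouts = 5, seed = 1,
                         diffusion = 0.00035, chi0 = 0.38, chi_sat = 0.6,
                         rho = 0.34, taf_uptake = 0.1,
                         fib_production = 0.05, fib_degradation = 0.1,
                         taf_scale = 0.2, fib_scale = 2,
                         fib_level = 0.75,
                         k_step = NULL, branch_ages = 10,
                         branch_taf = c(0.25, 0.45, 0.6, 0.68),
                         branch_prob = c(0, 0.2, 0.3, 0.4, 1),
                         max_steps = 2000) {
  stopifnot(n_sprouts >= 1, diffusion > 0, chi0 >= 0, rho >= 0,
            length(branch_prob) == length(branch_taf) + 1,
            all(branch_prob >= 0 & branch_prob <= 1))
  structure(list(n_sprouts = as.integer(n_sprouts), seed = as.integer(seed),
                 diffusion = diffusion, chi0 = chi0, chi_sat = chi_sat,
                 rho = rho, taf_uptake = taf_uptake,
                 fib_production = fib_production,
                 fib_degradation = fib_degradation,
                 taf_scale = taf_scale, fib_scale = fib_scale,
                 fib_level = fib_level, k_step = k_step,
                 branch_ages = as.integer(branch_ages),
                 branch_taf = branch_taf, branch_prob = branch_prob,
                 max_steps = as.integer(max_steps)),
            class = "angio_params")
}

#' Initial TAF and fibronectin fields
#'
#' TAF is 1 inside the tumor and decays exponentially with distance from
#' the tumor boundary; fibronectin is maximal at the parent vessel (left
#' edge) and decays with x. Both fields are dimensionless in `[0, 1]`
#' (fibronectin in `[0, fib_level]`).
#'
#' @param params an `angio_params`.
#' @param domain a `tissue_domain` (its tumor mask defines the TAF source).
#' @return list of matrices `taf` and `fib` (nx by ny).
#' @export
init_fields <- function(params, domain) {
  if (!any(domain$tumor_mask)) stop("empty tumor mask")
  L <- domain$length
  # normalized distance from each cell center to the tumor disc edge
  dx <- outer(domain$xc - domain$tumor_center[1], rep(1, domain$ny))
  dy <- outer(rep(1, domain$nx), domain$yc - domain$tumor_center[2])
  d <- pmax(sqrt(dx^2 + dy^2) - domain$tumor_radius, 0) / L
  taf <- exp(-d^2 / params$taf_scale)
  x <- outer(domain$xc / L, rep(1, domain$ny))
  fib <- params$fib_level * exp(-x^2 / params$fib_scale)
  list(taf = taf, fib = fib)
}

#' Movement probabilities of an endothelial tip
#'
#' Five-point stencil probabilities (stay, +x, -x, +y, -y) of the discrete
#' tip-migration model: random motility plus saturating chemotaxis up the
#' TAF gradient plus haptotaxis up the fibronectin gradient. Moves leaving
#' the grid are masked; negative stencil coefficients are truncated at
#' zero and the five weights renormalized to sum to one.
#'
#' @param i,j cell index of the tip.
#' @param fields list with `taf` and `fib` matrices.
#' @param params an `angio_params`.
#' @return named numeric vector `c(stay, right, left, up, down)` summing
#'   to 1.
#' @export
movement_probabilities <- function(i, j, fields, params) {
  taf <- fields$taf; fib <- fields$fib
  nx <- nrow(taf); ny <- ncol(taf)
  if (i < 1 || i > nx || j < 1 || j > ny) stop("tip outside grid")
  h <- 1 / nx
  k <- if (is.null(params$k_step)) h^2 / (4 * params$diffusion) else
    params$k_step
  at <- function(M, ii, jj) M[pmin(pmax(ii, 1), nx), pmin(pmax(jj, 1), ny)]
  chi <- params$chi0 / (1 + params$chi_sat * taf[i, j])
  kh2 <- k / h^2
  drift <- function(fp, fm, gp, gm) {
    kh2 * (params$diffusion +
             chi / 4 * (fp - fm) + params$rho / 4 * (gp - gm))
  }
  p_r <- drift(at(taf, i + 1, j), at(taf, i - 1, j),
               at(fib, i + 1, j), at(fib, i - 1, j))
  p_l <- drift(at(taf, i - 1, j), at(taf, i + 1, j),
               at(fib, i - 1, j), at(fib, i + 1, j))
  p_u <- drift(at(taf, i, j + 1), at(taf, i, j - 1),
               at(fib, i, j + 1), at(fib, i, j - 1))
  p_d <- drift(at(taf, i, j - 1), at(taf, i, j + 1),
               at(fib, i, j - 1), at(fib, i, j + 1))
  p <- c(right = p_r, left = p_l, up = p_u, down = p_d)
  p[p < 0] <- 0
  p0 <- max(0, 1 - sum(p))
  # mask moves that would leave the grid
  if (i == nx) p["right"] <- 0
  if (i == 1) p["left"] <- 0
  if (j == ny) p["up"] <- 0
  if (j == 1) p["down"] <- 0
  p <- c(stay = p0, p)
  s <- sum(p)
  if (s <= 0) stop("all moves masked for tip")
  p / s
}

#' Grow a tumor-induced capillary network
#'
#' Lattice random walk of `n_sprouts` endothelial tips starting from
#' evenly spaced root nodes on the parent vessel, biased toward the tumor
#' by the TAF field. A tip stepping onto a cell vascularized by a
#' different sprout or by the parent vessel fuses the two vessels
#' (anastomosis) and the tip retires; stepping onto its own sprout's
#' trail creates a junction (an intra-sprout loop) through which the tip
#' keeps migrating. The immediate back-step is forbidden. Tips branch with a probability
#' increasing with local TAF once older than a minimum age, and stop on
#' contact with the tumor. TAF is consumed and fibronectin
#' produced/degraded at occupied cells. The walk is deterministic given
#' `params$seed`.
#'
#' @param params an `angio_params`.
#' @param domain a `tissue_domain`.
#' @param D_capillary initial capillary diameter, m.
#' @param D_parent parent diameter, m.
#' @return a `vessel_network` containing the parent chain plus the grown
#'   capillaries; attributes `n_anastomoses` (cross-sprout tip fusions),
#'   `n_self_junctions` (intra-sprout loop junctions) and `sprout_rows`
#'   (parent rows the sprouts started from).
#' @export
grow_network <- function(params, domain, D_capillary = 12e-6,
                         D_parent = 28e-6) {
  set.seed(params$seed)
  nx <- domain$nx; ny <- domain$ny
  fields <- init_fields(params, domain)
  cell_id <- function(i, j) i + (j - 1L) * nx
  occup <- matrix(0L, nx, ny)   # 0 free, else lineage id (parent = 1)
  occup[1, ] <- 1L
  # evenly spaced sprout roots on the parent, away from the two ends
  rows <- round(seq(1, ny, length.out = params$n_sprouts + 2))
  rows <- as.integer(rows[2:(params$n_sprouts + 1)])
  n0 <- params$n_sprouts
  ti <- rep(2L, n0); tj <- rows            # first extension into the tissue
  pi_ <- rep(1L, n0); pj_ <- rows
  age <- rep(0L, n0); bid <- seq_len(n0) + 1L
  ecap <- 8L * params$max_steps
  edges_a <- integer(ecap); edges_b <- integer(ecap); ne <- 0L
  add_edge <- function(i1, j1, i2, j2) {
    ne <<- ne + 1L
    if (ne > length(edges_a)) {
      edges_a <<- c(edges_a, integer(ecap)); edges_b <<- c(edges_b, integer(ecap))
    }
    edges_a[ne] <<- cell_id(i1, j1); edges_b[ne] <<- cell_id(i2, j2)
  }
  for (t in seq_len(n0)) {
    add_edge(pi_[t], pj_[t], ti[t], tj[t])
    occup[ti[t], tj[t]] <- bid[t]
  }
  n_anast <- 0L
  n_self <- 0L
  k_eff <- if (is.null(params$k_step)) (1 / nx)^2 / (4 * params$diffusion)
           else params$k_step
  di <- c(0L, 1L, -1L, 0L, 0L); dj <- c(0L, 0L, 0L, 1L, -1L)
  for (step in seq_len(params$max_steps)) {
    if (!length(ti)) break
    alive <- rep(TRUE, length(ti))
    b_i <- integer(); b_j <- integer(); b_pi <- integer(); b_pj <- integer()
    b_age <- integer(); b_bid <- integer()
    for (t in seq_along(ti)) {
      ci <- ti[t]; cj <- tj[t]
      # local field kinetics at the occupied cell
      fields$taf[ci, cj] <- fields$taf[ci, cj] *
        max(0, 1 - params$taf_uptake * k_eff)
      fields$fib[ci, cj] <- fields$fib[ci, cj] +
        k_eff * (params$fib_production -
                   params$fib_degradation * fields$fib[ci, cj])
      branch <- FALSE
      if (age[t] >= params$branch_ages) {
        bp <- params$branch_prob[findInterval(fields$taf[ci, cj],
                                              params$branch_taf) + 1L]
        branch <- runif(1) < bp
      }
      p <- movement_probabilities(ci, cj, fields, params)
      p[1] <- 0  # a tip always attempts to extend
      # forbid only the immediate back-step
      for (d in 2:5) {
        if (ci + di[d] == pi_[t] && cj + dj[d] == pj_[t]) p[d] <- 0
      }
      if (sum(p) <= 0) { alive[t] <- FALSE; next }  # stuck: tip dies
      n_moves <- if (branch) 2L else 1L
      taken_i <- -1L; taken_j <- -1L
      moved <- FALSE
      for (m in seq_len(n_moves)) {
        q <- p
        if (taken_i > 0L) {
          for (d in 2:5) {
            if (ci + di[d] == taken_i && cj + dj[d] == taken_j) q[d] <- 0
          }
        }
        if (sum(q) <= 0) next
        sel <- sample.int(5L, 1L, prob = q)
        ni <- ci + di[sel]; nj <- cj + dj[sel]
        add_edge(ci, cj, ni, nj)
        taken_i <- ni; taken_j <- nj
        if (occup[ni, nj] != 0L && occup[ni, nj] != bid[t]) {
          # terminal anastomosis with another sprout or the parent
          n_anast <- n_anast + 1L
          next
        }
        if (occup[ni, nj] == bid[t]) {
          # junction with the tip's own sprout: the migrating tip passes
          # through the loop; a freshly spawned branch does not take root
          # inside the existing mesh
          n_self <- n_self + 1L
          if (m == 2L) next
        }
        occup[ni, nj] <- bid[t]
        if (domain$tumor_mask[ni, nj]) next  # tumor contact: branch retires
        b_i <- c(b_i, ni); b_j <- c(b_j, nj)
        b_pi <- c(b_pi, ci); b_pj <- c(b_pj, cj)
        b_age <- c(b_age, if (branch) 0L else age[t] + 1L)
        b_bid <- c(b_bid, bid[t])
        moved <- TRUE
      }
      alive[t] <- FALSE  # the tip either moved (reborn in b_*) or retired
      if (!moved) next
    }
    ti <- b_i; tj <- b_j; pi_ <- b_pi; pj_ <- b_pj
    age <- b_age; bid <- b_bid
  }
  edges_a <- edges_a[seq_len(ne)]; edges_b <- edges_b[seq_len(ne)]
  # assemble network: parent chain + unique lattice edges
  ea <- pmin(edges_a, edges_b); eb <- pmax(edges_a, edges_b)
  dup <- duplicated(paste(ea, eb)) | ea == eb
  ea <- ea[!dup]; eb <- eb[!dup]
  used <- sort(unique(c(cell_id(1L, seq_len(ny)), ea, eb)))
  ij <- cbind(((used - 1L) %% nx) + 1L, ((used - 1L) %/% nx) + 1L)
  nodes <- data.frame(id = used,
                      x = (ij[, 1] - 0.5) * domain$h,
                      y = (ij[, 2] - 0.5) * domain$h,
                      role = "interior", pressure = NA_real_)
  nodes$role[nodes$id == cell_id(1L, 1L)] <- "inlet"
  nodes$role[nodes$id == cell_id(1L, ny)] <- "outlet"
  parent_a <- cell_id(1L, seq_len(ny - 1L))
  parent_b <- cell_id(1L, seq_len(ny - 1L) + 1L)
  edges <- data.frame(from = c(parent_a, ea), to = c(parent_b, eb),
                      is_parent = c(rep(TRUE, ny - 1L),
                                    rep(FALSE, length(ea))))
  # drop any duplicate of a parent edge produced by a walker fusing along
  # the parent column
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  edges <- edges[!duplicated(key), ]
  net <- build_network(nodes, edges, D_capillary = D_capillary,
                       D_parent = D_parent)
  attr(net, "n_anastomoses") <- n_anast
  attr(net, "n_self_junctions") <- n_self
  attr(net, "sprout_rows") <- rows
  net
}
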