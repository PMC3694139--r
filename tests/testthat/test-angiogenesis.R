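test_that("initial chemical fields have the right geometry", {
  dom <- tissue_domain()
  par <- angio_params()
  f <- init_fields(par, dom)
  # TAF grows toward the tumor in every row
  expect_true(all(f$taf[dom$nx, ] > f$taf[1, ]))
  expect_true(all(f$taf >= 0 & f$taf <= 1))
  # interior x-derivative of TAF is positive everywhere (finite
  # differences along every row)
  expect_true(all(diff(f$taf) > 0 | abs(diff(f$taf)) < 1e-14))
  # fibronectin decays away from the parent vessel
  expect_true(all(f$fib[1, ] > f$fib[dom$nx, ]))
  # tumor covering the whole domain saturates TAF
  dom_all <- tissue_domain(nx = 10, ny = 10, length_m = 10 * h_fix,
                           tumor_radius = 1, tumor_center = c(1e-4, 1e-4))
  f_all <- init_fields(par, dom_all)
  expect_true(all(f_all$taf == 1))
  dom_none <- dom_all
  dom_none$tumor_mask[] <- FALSE
  expect_error(init_fields(par, dom_none), "tumor mask")
})

test_that("movement probabilities are a proper distribution biased up the
           TAF gradient", {
  par <- angio_params()
  nx <- 30
  # uniform fields: the four moves are equally likely
  uni <- list(taf = matrix(0.5, nx, nx), fib = matrix(0.3, nx, nx))
  p <- movement_probabilities(15, 15, uni, par)
  expect_equal(sum(p), 1)
  expect_equal(p[["right"]], p[["left"]])
  expect_equal(p[["up"]], p[["down"]])

  # normalization over many random states
  set.seed(5)
  for (i in 1:200) {
    f <- list(taf = matrix(runif(nx * nx), nx, nx),
              fib = matrix(runif(nx * nx), nx, nx))
    ij <- sample(2:(nx - 1), 2, replace = TRUE)
    p <- movement_probabilities(ij[1], ij[2], f, par)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }

  # rightward TAF gradient with flat fibronectin biases the walk right;
  # the margin matches a direct evaluation of the stencil coefficients
  taf <- matrix(rep(seq(0, 0.9, length.out = nx), nx), nx, nx)
  f <- list(taf = taf, fib = matrix(0.3, nx, nx))
  i <- 15; j <- 15
  p <- movement_probabilities(i, j, f, par)
  expect_gt(p[["right"]], p[["left"]])
  h <- 1 / nx
  k <- h^2 / (4 * par$diffusion)
  chi <- par$chi0 / (1 + par$chi_sat * taf[i, j])
  kh2 <- k / h^2
  dtaf <- taf[i + 1, j] - taf[i - 1, j]
  raw <- pmax(c(kh2 * (par$diffusion + chi / 4 * dtaf),   # right
                kh2 * (par$diffusion - chi / 4 * dtaf),   # left
                kh2 * par$diffusion,                      # up
                kh2 * par$diffusion), 0)                  # down
  stay <- max(0, 1 - sum(raw))
  margin <- (raw[1] - raw[2]) / (stay + sum(raw))
  expect_equal(p[["right"]] - p[["left"]], margin, tolerance = 1e-10)

  # edge masking: at the right boundary the rightward move is impossible
  p_edge <- movement_probabilities(nx, 15, f, par)
  expect_equal(p_edge[["right"]], 0)
  expect_equal(sum(p_edge), 1)
})

test_that("the generator is seeded, rooted and lattice-consistent", {
  dom <- tissue_domain()
  for (ns in c(5, 10)) {
    net <- grow_network(angio_params(n_sprouts = ns, seed = 9), dom)
    # root count: sprout roots are the parent nodes with lateral segments
    roots <- attr(net, "sprout_rows")
    expect_length(roots, ns)
    on_parent <- net$nodes$x < dom$h
    root_ids <- net$nodes$id[on_parent][roots]
    lateral <- !net$segments$is_parent &
      (net$segments$from %in% net$nodes$id[on_parent] |
       net$segments$to %in% net$nodes$id[on_parent])
    expect_gte(sum(lateral), ns)
  }

  # determinism: identical seeds give identical networks
  a <- grow_network(angio_params(n_sprouts = 5, seed = 4), dom)
  b <- grow_network(angio_params(n_sprouts = 5, seed = 4), dom)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$segments, b$segments)
  c_ <- grow_network(angio_params(n_sprouts = 5, seed = 5), dom)
  expect_false(identical(a$segments, c_$segments))

  # segments are unit lattice edges with no duplicates
  fi <- match(a$segments$from, a$nodes$id)
  ti <- match(a$segments$to, a$nodes$id)
  len <- sqrt((a$nodes$x[fi] - a$nodes$x[ti])^2 +
              (a$nodes$y[fi] - a$nodes$y[ti])^2)
  expect_equal(len, rep(dom$h, length(len)), tolerance = 1e-12)
  key <- paste(pmin(a$segments$from, a$segments$to),
               pmax(a$segments$from, a$segments$to))
  expect_false(any(duplicated(key)))
})

test_that("sprouts advance toward the tumor under the TAF drift", {
  dom <- tissue_domain()
  # ensemble of seeds: the capillary front must reach well past the
  # domain midline, and longer growth never moves the front backwards
  fronts <- vapply(1:8, function(s) {
    net <- grow_network(angio_params(n_sprouts = 5, seed = s), dom)
    max(net$nodes$x[match(unique(c(net$segments$from, net$segments$to)),
                          net$nodes$id)])
  }, numeric(1))
  expect_true(all(fronts > 0.6 * dom$length))

  short <- grow_network(angio_params(n_sprouts = 5, seed = 2,
                                     max_steps = 40), dom)
  long <- grow_network(angio_params(n_sprouts = 5, seed = 2,
                                    max_steps = 160), dom)
  mean_x <- function(n) mean(n$nodes$x[!n$nodes$x < dom$h])
  expect_gte(mean_x(long), mean_x(short))
})

test_that("with branching disabled the generator adds no branch points of
           its own", {
  dom <- tissue_domain()
  par <- angio_params(n_sprouts = 4, seed = 6,
                      branch_prob = c(0, 0, 0, 0, 0), max_steps = 300)
  net <- grow_network(par, dom)
  deg <- node_degrees(net)
  off_parent <- net$nodes$x >= dom$h
  n_high <- sum(deg[off_parent] > 2)
  # every extra junction must be accounted for by a fusion event (each
  # anastomosis or self-junction touches at most two nodes)
  n_events <- attr(net, "n_anastomoses") + attr(net, "n_self_junctions")
  expect_lte(n_high, 2 * n_events)
})
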