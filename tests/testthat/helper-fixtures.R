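# Hand-checkable network fixtures and an independent dense linear solver
# used as the oracle for the nodal pressure solve.

h_fix <- 2e-5  # lattice spacing of the fixtures, m

# Straight chain of n segments along x, inlet at the left end, outlet at
# the right end.
chain_network <- function(n_seg, D = 12e-6, L = h_fix, H = 0.45,
                          mu = 2e-3, y = 5 * h_fix) {
  nodes <- data.frame(id = seq_len(n_seg + 1),
                      x = (seq_len(n_seg + 1) - 0.5) * L,
                      y = y,
                      role = c("inlet", rep("interior", n_seg - 1), "outlet"))
  edges <- data.frame(from = seq_len(n_seg), to = seq_len(n_seg) + 1,
                      D = D, L = L, H = H, mu = mu)
  build_network(nodes, edges)
}

# Diamond loop: inlet - two parallel limbs of two segments each - outlet.
diamond_network <- function(D = 12e-6, L = h_fix, mu = 2e-3) {
  nodes <- data.frame(id = 1:4,
                      x = c(1, 2, 2, 3) * L,
                      y = c(2, 1, 3, 2) * L,
                      role = c("inlet", "interior", "interior", "outlet"))
  edges <- data.frame(from = c(1, 1, 2, 3), to = c(2, 3, 4, 4),
                      D = D, L = L, H = 0.45, mu = mu)
  build_network(nodes, edges)
}

# Y-bifurcation: one feed segment splitting into two daughters with
# controllable diameters.
y_network <- function(D_feed = 12e-6, D1 = 12e-6, D2 = 12e-6, L = h_fix,
                      mu = 2e-3) {
  nodes <- data.frame(id = 1:4,
                      x = c(1, 2, 3, 3) * L,
                      y = c(2, 2, 1, 3) * L,
                      role = c("inlet", "interior", "outlet", "outlet"))
  edges <- data.frame(from = c(1, 2, 2), to = c(2, 3, 4),
                      D = c(D_feed, D1, D2), L = L, H = 0.45, mu = mu)
  build_network(nodes, edges)
}

# Independent dense solve of the nodal balance equations, re-derived from
# scratch: interior node c satisfies
#   sum_s g_s (P_k - P_c) - 0.5 sum_s lambda_s ((P_c + P_k)/2 - Pe_s) = 0.
dense_nodal_oracle <- function(net, g, lambda, Pe, P_inlet, P_outlet) {
  nodes <- net$nodes
  segs <- net$segments
  n <- nrow(nodes)
  A <- matrix(0, n, n)
  b <- numeric(n)
  fi <- match(segs$from, nodes$id)
  ti <- match(segs$to, nodes$id)
  for (s in seq_len(nrow(segs))) {
    for (pair in list(c(fi[s], ti[s]), c(ti[s], fi[s]))) {
      c_ <- pair[1]; k_ <- pair[2]
      A[c_, k_] <- A[c_, k_] + g[s] - lambda[s] / 4
      A[c_, c_] <- A[c_, c_] - g[s] - lambda[s] / 4
      b[c_] <- b[c_] - lambda[s] / 2 * Pe[s]
    }
  }
  for (i in seq_len(n)) {
    if (nodes$role[i] %in% c("inlet", "outlet")) {
      A[i, ] <- 0
      A[i, i] <- 1
      b[i] <- if (nodes$role[i] == "inlet") P_inlet else P_outlet
    }
  }
  solve(A, b)
}

# Brute-force enumeration of all cycles' edges on small graphs: an edge
# lies on a cycle iff removing it keeps its endpoints connected.
edges_on_cycles <- function(net) {
  segs <- net$segments
  on_cycle <- logical(nrow(segs))
  for (s in seq_len(nrow(segs))) {
    rest <- segs[-s, , drop = FALSE]
    reach <- segs$from[s]
    repeat {
      nb <- unique(c(rest$to[rest$from %in% reach],
                     rest$from[rest$to %in% reach]))
      new <- setdiff(nb, reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    on_cycle[s] <- segs$to[s] %in% reach
  }
  segs$id[on_cycle]
}

small_domain <- function(nx = 20, ny = 20) {
  tissue_domain(nx = nx, ny = ny, length_m = nx * h_fix,
                tumor_radius = 4 * h_fix)
}
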