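# tree fixtures built in code

default_inlet_tree <- function(r0 = 0.075, Q_in = 0.002, gamma = 3) {
  vascular_tree(c(0, 0.5, 0.5), c(0.4, 0.5, 0.5), r0 = r0, Q_in = Q_in,
                gamma = gamma)
}

unit_box <- function(seed = 1L) box_domain(c(0, 0, 0), c(1, 1, 1), seed = seed)
fig_box <- function(seed = 1L) box_domain(c(0, 0, 0), c(4, 1, 1), seed = seed)

# grow a small random tree inside the 4x1x1 box (deterministic given seed)
grown_tree <- function(n_add = 20L, seed = 1L, viscosity = viscosity_model(),
                       domain = fig_box()) {
  st <- stage_config(N = n_add, viscosity = viscosity)
  grow(default_inlet_tree(), domain, st, seed = seed)
}

# hand-built perfect binary tree with 8 terminals (15 segments): the root
# splits into balanced generations with explicitly chosen coordinates
perfect_tree_8 <- function() {
  tr <- vascular_tree(c(0, 0, 0), c(1, 0, 0), r0 = 0.1, Q_in = 1)
  # generation 1
  a <- add_terminal(tr, 1L, c(0.5, 0, 0), c(1, 0.8, 0))
  tr <- a$tree
  # generation 2: split both gen-1 daughters
  b <- add_terminal(tr, a$sibling_id, c(0.75, 0, 0), c(1.2, -0.5, 0))
  tr <- b$tree
  cc <- add_terminal(tr, a$terminal_id, c(0.75, 0.4, 0), c(0.6, 0.9, 0))
  tr <- cc$tree
  # generation 3: split the four gen-2 daughters
  leaves <- list(
    list(b$sibling_id, c(0.9, 0, 0), c(1.1, 0.3, 0.4)),
    list(b$terminal_id, c(0.975, -0.25, 0), c(1.4, -0.3, 0.3)),
    list(cc$sibling_id, c(0.875, 0.6, 0), c(1.3, 0.9, 0.2)),
    list(cc$terminal_id, c(0.675, 0.65, 0), c(0.4, 1.0, 0.3)))
  for (L in leaves) tr <- add_terminal(tr, L[[1]], L[[2]], L[[3]])$tree
  assign_terminal_flows(tr)
}

# 3-level asymmetric toy tree with printed coordinates (radii unset until
# rescaling)
asymmetric_toy_tree <- function() {
  tr <- vascular_tree(c(0, 0, 0), c(1, 0, 0), r0 = 0.2, Q_in = 1)
  tr <- add_terminal(tr, 1L, c(0.6, 0, 0), c(1.0, 0.7, 0))$tree
  tr <- add_terminal(tr, 3L, c(0.85, 0, 0), c(1.3, -0.6, 0.2))$tree
  tr <- add_terminal(tr, 7L, c(1.05, -0.27, 0.09), c(0.8, -0.8, -0.3))$tree
  assign_terminal_flows(tr)
}

# independent full-pressure-solve oracle: sparse linear system on nodal
# pressures (inlet node pinned to zero), Matrix-free via base solve()
r_pressure_oracle <- function(tree) {
  n <- n_segments(tree)
  # nodes: one per vessel distal end + one inlet node
  pidx <- match(tree$parent, tree$id)
  lens <- segment_lengths(tree)
  Rv <- 8 * tree$mu * lens / (pi * tree$r^4) # dyn s / cm^5
  # unknowns: distal pressure of each vessel; proximal = parent's distal (or 0)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    A[i, i] <- 1
    if (!is.na(pidx[i])) A[i, pidx[i]] <- -1
    b[i] <- -tree$Q[i] * Rv[i]
  }
  pd <- solve(A, b) * 7.50062e-4
  pp <- ifelse(is.na(pidx), 0, pd[pidx])
  list(p_prox = pp, p_dist = pd)
}

# independent Strahler oracle: plain recursion
r_strahler_oracle <- function(tree) {
  i1 <- match(tree$c1, tree$id)
  i2 <- match(tree$c2, tree$id)
  rec <- function(i) {
    if (is.na(i1[i])) return(0L)
    a <- rec(i1[i]); b <- rec(i2[i])
    if (a == b) a + 1L else max(a, b)
  }
  vapply(seq_len(n_segments(tree)), rec, 1L)
}
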