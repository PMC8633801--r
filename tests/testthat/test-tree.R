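# vessel tree data model: topology edits, flow bookkeeping, radius rescaling

test_that("terminal addition obeys the 2N-1 law and updates counts", {
  tr <- default_inlet_tree()
  expect_equal(n_segments(tr), 1L)
  expect_equal(n_terminals(tr), 1L)
  a <- add_terminal(tr, 1L, c(0.2, 0.5, 0.5), c(0.3, 0.8, 0.5))
  expect_equal(n_terminals(a$tree), 2L)
  expect_equal(n_segments(a$tree), 3L)
  # randomized sequence of k additions, recount by traversal each time
  set.seed(7)
  tr <- default_inlet_tree()
  for (k in 1:25) {
    term <- terminal_ids(tr)
    pid <- sample(tr$id, 1)
    i <- match(pid, tr$id)
    xb <- tr$xp[i, ] + runif(1, 0.3, 0.7) * (tr$xd[i, ] - tr$xp[i, ]) +
      runif(3, -0.01, 0.01)
    xn <- xb + runif(3, -0.2, 0.2)
    tr <- add_terminal(tr, pid, xb, xn)$tree
    expect_equal(n_segments(tr), 2L * (k + 1L) - 1L)
    expect_identical(vasctree:::.recount_nterm(tr), tr$nterm)
  }
  validate_tree(tr)
})

test_that("ids are never reused and the split vessel's id is retired", {
  tr <- default_inlet_tree()
  a <- add_terminal(tr, 1L, c(0.2, 0.5, 0.5), c(0.3, 0.8, 0.5))
  expect_false(1L %in% a$tree$id)
  expect_setequal(a$tree$id, c(a$stub_id, a$sibling_id, a$terminal_id))
  b <- add_terminal(a$tree, a$sibling_id, c(0.3, 0.5, 0.5), c(0.35, 0.2, 0.5))
  expect_false(a$sibling_id %in% b$tree$id)
  expect_equal(sort(setdiff(b$tree$id, a$tree$id)),
               c(b$stub_id, b$sibling_id, b$terminal_id))
})

test_that("degenerate additions are rejected", {
  tr <- default_inlet_tree()
  expect_error(add_terminal(tr, 99L, c(0.2, 0.5, 0.5), c(0.3, 0.8, 0.5)),
               "unknown parent")
  expect_error(add_terminal(tr, 1L, c(0, 0.5, 0.5), c(0.3, 0.8, 0.5)),
               "endpoint")
  expect_error(add_terminal(tr, 1L, c(0.2, 0.5, 0.5), c(0.2, 0.5, 0.5)),
               "bifurcation")
})

test_that("terminal flows: uniform and mixed policies conserve Q_in", {
  # Q_in = 2, four terminals, uniform -> 0.5 each
  tr <- vascular_tree(c(0, 0, 0), c(1, 0, 0), r0 = 0.1, Q_in = 2)
  tr <- add_terminal(tr, 1L, c(0.5, 0, 0), c(1, 1, 0))$tree
  for (tid in terminal_ids(tr)) {
    i <- match(tid, tr$id)
    tr <- add_terminal(tr, tid, (tr$xp[i, ] + tr$xd[i, ]) / 2 + c(0, 0, 0.01),
                       tr$xd[i, ] + c(0, 0, 0.5))$tree
  }
  tr <- assign_terminal_flows(tr)
  expect_equal(n_terminals(tr), 4L)
  expect_equal(unname(tr$Q[match(terminal_ids(tr), tr$id)]), rep(0.5, 4))
  expect_equal(tr$Q[match(tr$root, tr$id)], 2)
  # flow conservation at bifurcations, exact
  int <- which(!is.na(tr$c1))
  expect_identical(tr$Q[int],
                   tr$Q[match(tr$c1[int], tr$id)] +
                     tr$Q[match(tr$c2[int], tr$id)])
  # mixed: 3 fixed at 0.1, Q_in = 1, 7 free -> each free gets (1-0.3)/7 = 0.1
  tr2 <- grown_tree(9L, seed = 2)
  expect_equal(n_terminals(tr2), 10L)
  fixed_ids <- terminal_ids(tr2)[1:3]
  fixed <- rep(0.1, 3)
  names(fixed) <- fixed_ids
  tr2$Q_in <- 1
  tr2 <- assign_terminal_flows(tr2, fixed = fixed)
  q <- tr2$Q[match(terminal_ids(tr2), tr2$id)]
  expect_equal(unname(q), rep(0.1, 10), tolerance = 1e-15)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  # non-positive remainder errors
  names(fixed) <- fixed_ids
  fixed[] <- 0.5
  expect_error(assign_terminal_flows(tr2, fixed = fixed), "non-positive")
})

test_that("terminal flow arithmetic matches the scalability inlet setting", {
  # Q_in = 2 mm^3/s uniformly over 1e5 terminals gives 2e-5 mm^3/s each;
  # checked through the same computation at a reduced terminal count
  tr <- grown_tree(99L, seed = 3)
  tr$Q_in <- 0.002 # 2 mm^3/s in cm^3/s
  tr <- assign_terminal_flows(tr)
  expect_equal(unname(tr$Q[match(terminal_ids(tr), tr$id)]),
               rep(0.002 / 100, 100), tolerance = 1e-15)
})

test_that("radius rescaling: symmetry, Murray law, root radius, idempotence", {
  # symmetric bifurcation, gamma = 3 -> beta = 2^(-1/3) on both daughters
  tr <- vascular_tree(c(0, 0, 0), c(1, 0, 0), r0 = 0.1, Q_in = 1)
  tr <- add_terminal(tr, 1L, c(0.5, 0, 0), c(1, 0.5, 0))$tree
  # make daughters geometrically identical in length
  i1 <- match(tr$c1[match(tr$root, tr$id)], tr$id)
  i2 <- match(tr$c2[match(tr$root, tr$id)], tr$id)
  tr$xd[i2, ] <- tr$xp[i2, ] + c(0.5, -0.5, 0) *
    sqrt(sum((tr$xd[i1, ] - tr$xp[i1, ])^2)) / sqrt(0.5)
  tr <- assign_terminal_flows(tr)
  tr <- rescale_radii(tr)
  expect_equal(tr$beta[i1], 2^(-1 / 3), tolerance = 1e-12)
  expect_equal(tr$beta[i2], 2^(-1 / 3), tolerance = 1e-12)
  # root radius is a fixed input
  root <- vascular_tree(c(0, 0, 0), c(1, 0, 0), r0 = 0.075, Q_in = 0.002)
  root <- rescale_radii(assign_terminal_flows(root))
  expect_identical(root$r, 0.075)
  # Murray residual and idempotence on a grown tree
  tr <- grown_tree(40L, seed = 5)
  g <- tr$gamma
  int <- which(!is.na(tr$c1))
  ia <- match(tr$c1[int], tr$id); ib <- match(tr$c2[int], tr$id)
  resid <- abs(tr$r[int]^g - tr$r[ia]^g - tr$r[ib]^g) / tr$r[int]^g
  expect_lt(max(resid), 1e-10)
  tr2 <- rescale_radii(tr)
  expect_lt(max(abs(tr2$r - tr$r) / tr$r), 1e-12)
})

test_that("rescaled radii equalize terminal pressures (closure oracle)", {
  # equal-terminal-pressure closure: after rescaling, a full independent
  # linear pressure solve must give identical pressure at every terminal
  for (seed in 1:3) {
    tr <- grown_tree(15L, seed = seed)
    sol <- r_pressure_oracle(tr)
    tp <- sol$p_dist[match(terminal_ids(tr), tr$id)]
    expect_lt(diff(range(tp)) / abs(mean(tp)), 1e-6)
  }
  # and on the printed asymmetric toy tree
  toy <- rescale_radii(asymmetric_toy_tree())
  sol <- r_pressure_oracle(toy)
  tp <- sol$p_dist[match(terminal_ids(toy), toy$id)]
  expect_lt(diff(range(tp)) / abs(mean(tp)), 1e-8)
  # daughter radius ratio satisfies (r_l/r_r)^4 = (Q_l R*_l)/(Q_r R*_r):
  # verified through equal daughter-subtree pressure drops in the oracle
  expect_equal(toy$r[match(toy$root, toy$id)], 0.2)
})

test_that("generations count bifurcations from the root", {
  tr <- default_inlet_tree()
  expect_equal(generation_of(tr), 0L)
  a <- add_terminal(tr, 1L, c(0.2, 0.5, 0.5), c(0.3, 0.8, 0.5))
  g <- generation_of(a$tree)
  expect_equal(g[match(a$stub_id, a$tree$id)], 0L)      # stub keeps gen 0
  expect_equal(g[match(a$sibling_id, a$tree$id)], 1L)   # daughters one deeper
  expect_equal(g[match(a$terminal_id, a$tree$id)], 1L)
  p8 <- perfect_tree_8()
  expect_equal(max(generation_of(p8)), 3L) # log2(8) levels
  expect_equal(min(generation_of(p8)), 0L)
})

test_that("validate_tree flags broken invariants", {
  tr <- grown_tree(10L, seed = 1)
  expect_true(validate_tree(tr, hemodynamic = TRUE))
  bad <- tr
  bad$r[3] <- -1
  expect_error(validate_tree(bad), "radius")
  bad2 <- tr
  bad2$nterm[1] <- bad2$nterm[1] + 1L
  expect_error(validate_tree(bad2), "inconsistent")
})
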