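# viscosity law, Poiseuille resistances, pressure solve, fixed point

test_that("viscosity: constant model, closed form, continuity", {
  cm <- viscosity_model("constant", mu_cP = 3.6)
  expect_equal(viscosity(c(5, 50, 500), cm), rep(3.6, 3))
  dm <- viscosity_model("diameter", mu_plasma_cP = 1.2, hd = 0.45)
  # independent re-evaluation of the in-vitro relative viscosity law
  r_visc <- function(d, hd = 0.45, mu_plasma = 1.2) {
    eta45 <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
    frac <- 1 / (1 + 1e-11 * d^12)
    C <- (0.8 + exp(-0.075 * d)) * (-1 + frac) + frac
    mu_plasma * (1 + (eta45 - 1) * ((1 - hd)^C - 1) / ((1 - 0.45)^C - 1))
  }
  d <- c(3, 10, 40, 100, 300, 1000)
  expect_equal(viscosity(d, dm), r_visc(d), tolerance = 1e-12)
  # at reference haematocrit the law dips in the Fahraeus-Lindqvist range
  expect_lt(viscosity(10, dm), viscosity(500, dm))
  # continuity at d = 50 um
  eps <- 10^-(4:8)
  dv <- abs(viscosity(50 + eps, dm) - viscosity(50, dm))
  expect_true(all(diff(dv) < 0)) # shrinks as eps -> 0
  expect_lt(dv[length(dv)], 1e-6)
  # haematocrit dependence respected
  expect_gt(viscosity(40, viscosity_model("diameter", hd = 0.6)),
            viscosity(40, dm))
  expect_error(viscosity(0, dm), "positive")
})

test_that("segment resistance: quartic law, linearity, unit conversion", {
  expect_equal(segment_resistance(1, 0.2, 0.036),
               segment_resistance(1, 0.1, 0.036) / 16)
  expect_equal(segment_resistance(2, 0.1, 0.036),
               2 * segment_resistance(1, 0.1, 0.036))
  # hand computation: R = 8 mu l / (pi r^4) dyn s/cm^5, to mmHg s/cm^3
  expect_equal(segment_resistance(1, 0.1, 0.036),
               8 * 0.036 * 1 / (pi * 1e-4) * 7.50062e-4, tolerance = 1e-15)
  expect_error(segment_resistance(-1, 0.1, 0.036), "positive")
})

test_that("pressure solve: trivial cases and linear-system oracle", {
  # single segment with engineered Q * R = 1 mmHg drop
  tr <- vascular_tree(c(0, 0, 0), c(1, 0, 0), r0 = 0.1, Q_in = 1)
  tr <- assign_terminal_flows(tr)
  Rv <- segment_resistance(1, 0.1, tr$mu) # mmHg s / cm^3
  tr$Q_in <- 1 / Rv
  tr <- assign_terminal_flows(tr)
  sol <- solve_pressures(tr)
  expect_equal(sol$p_prox, 0)
  expect_equal(sol$p_dist, -1, tolerance = 1e-12)
  # symmetric 3-segment tree: both terminal pressures equal
  t3 <- vascular_tree(c(0, 0, 0), c(1, 0, 0), r0 = 0.1, Q_in = 1)
  t3 <- add_terminal(t3, 1L, c(0.5, 0, 0), c(1, 0.5, 0))$tree
  i1 <- match(t3$c1[match(t3$root, t3$id)], t3$id)
  i2 <- match(t3$c2[match(t3$root, t3$id)], t3$id)
  t3$xd[i2, ] <- t3$xp[i2, ] + c(0.5, -0.5, 0)
  t3$xd[i1, ] <- t3$xp[i1, ] + c(0.5, 0.5, 0)
  t3 <- rescale_radii(assign_terminal_flows(t3))
  s3 <- solve_pressures(t3)
  expect_equal(s3$p_dist[i1], s3$p_dist[i2], tolerance = 1e-14)
  # random trees vs the independent sparse-linear-system oracle
  sizes <- c(7L, 12L, 22L, 31L)
  for (seed in 1:4) {
    tr <- grown_tree(sizes[seed], seed = seed,
                     viscosity = viscosity_model("diameter"))
    sol <- solve_pressures(tr)
    ora <- r_pressure_oracle(tr)
    expect_equal(sol$p_dist, ora$p_dist, tolerance = 1e-8)
    expect_equal(sol$p_prox, ora$p_prox, tolerance = 1e-8)
    # pressure is non-increasing along every root-to-terminal path
    expect_true(all(sol$p_dist <= sol$p_prox))
  }
})

test_that("telescoping and power-dissipation identities hold", {
  tr <- grown_tree(30L, seed = 9, viscosity = viscosity_model("diameter"))
  sol <- solve_pressures(tr)
  # drop to each terminal = sum of per-segment Q*R along its path
  pidx <- match(tr$parent, tr$id)
  for (tid in terminal_ids(tr)) {
    i <- match(tid, tr$id)
    s <- 0
    j <- i
    while (!is.na(j)) {
      s <- s + tr$Q[j] * sol$resistance[j]
      j <- pidx[j]
    }
    expect_equal(-sol$p_dist[i], s, tolerance = 1e-12)
  }
  # total dissipation = sum of terminal outflow times terminal drop
  term <- match(terminal_ids(tr), tr$id)
  expect_equal(sum(tr$Q^2 * sol$resistance),
               sum(tr$Q[term] * (-sol$p_dist[term])), tolerance = 1e-8)
})

test_that("fixed point: constant model converges in one iteration", {
  tr <- grown_tree(12L, seed = 4)
  res <- fixed_point_viscosity_radii(tr, viscosity_model("constant"))
  expect_equal(attr(res$solution, "iterations"), 1L)
  expect_equal(res$tree$r, rescale_radii(tr)$r, tolerance = 1e-15)
})

test_that("fixed point: diameter model is self-consistent at tolerance", {
  tr <- grown_tree(25L, seed = 6)
  res <- fixed_point_viscosity_radii(tr, viscosity_model("diameter"),
                                     tol = 1e-10)
  t1 <- res$tree
  # one extra sweep changes no radius beyond tolerance
  t2 <- rescale_radii(assign_terminal_flows(t1))
  expect_lt(max(abs(t2$r - t1$r) / t1$r), 1e-6)
  # terminal pressures agree after convergence
  drops <- terminal_pressure_drops(t1)
  expect_lt(diff(range(drops)) / mean(drops), 1e-6)
})

test_that("fixed point: hitting the iteration cap raises with residuals", {
  # starting from constant-viscosity radii, one diameter-model sweep moves
  # the radii by far more than an extreme tolerance allows: hitting the
  # iteration cap must raise the documented non-convergence error carrying
  # the residual history
  tr <- grown_tree(15L, seed = 8) # grown under the constant model
  err <- tryCatch(
    fixed_point_viscosity_radii(tr, viscosity_model("diameter"),
                                tol = 1e-14, max_iter = 1L),
    error = identity)
  expect_s3_class(err, "vasctree_nonconvergence")
  expect_match(conditionMessage(err), "converge")
  expect_length(err$residuals, 1L)
  expect_gt(err$residuals[1], 1e-14)
})
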