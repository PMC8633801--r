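# partitioned growth: parent sets, flow conditions, record logging, merge

make_baseline <- function(n_term = 40L, seed = 3L) {
  dom <- fig_box()
  st <- stage_config(N = n_term - 1L, tag = "baseline")
  list(dom = dom,
       part = partition_axis_aligned(dom, c(4L, 1L, 1L)),
       tree = grow(default_inlet_tree(), dom, st, seed = seed))
}

test_that("partition parent sets follow the midpoint rule and are disjoint", {
  bl <- make_baseline()
  mids <- segment_midpoints(bl$tree)
  lab <- label_point(bl$part, mids)
  sets <- lapply(1:4, function(i) partition_parents(bl$tree, bl$part, i))
  # exhaustive classification oracle
  for (i in 1:4)
    expect_setequal(sets[[i]], bl$tree$id[!is.na(lab) & lab == i])
  # pairwise disjoint; union bounded by the segment count
  all_ids <- unlist(sets)
  expect_false(any(duplicated(all_ids)))
  expect_lte(length(all_ids), n_segments(bl$tree))
  # a vessel straddling a cell boundary belongs to its midpoint's cell only
  straddlers <- which(label_point(bl$part, bl$tree$xp) !=
                        label_point(bl$part, bl$tree$xd))
  expect_gt(length(straddlers), 0L)
  for (i in straddlers)
    expect_equal(sum(vapply(sets, function(s) bl$tree$id[i] %in% s, TRUE)), 1L)
  # an empty parent set is an explicit error
  tiny <- grow(default_inlet_tree(), bl$dom, stage_config(N = 2L), seed = 1)
  expect_error(partition_parents(tiny, bl$part, 4L), "no baseline vessel")
})

test_that("subdomain flow conditions freeze outside terminals exactly", {
  bl <- make_baseline()
  tr <- bl$tree
  for (i in 1:4) {
    fc <- subdomain_flow_conditions(tr, bl$part, i)
    # conservation: frozen sum + Q_part = Q_in exactly
    expect_identical(sum(fc$frozen) + fc$Q_part, tr$Q_in)
    expect_setequal(c(names(fc$frozen), as.character(fc$free_ids)),
                    as.character(terminal_ids(tr)))
  }
  # on a uniformly grown baseline over 4 equal cells, Q_part is close to
  # Q_in / 4 (sampling symmetry, wide tolerance)
  bl2 <- make_baseline(n_term = 120L, seed = 5)
  qp <- vapply(1:4, function(i)
    subdomain_flow_conditions(bl2$tree, bl2$part, i)$Q_part, 1.0)
  expect_equal(qp / bl2$tree$Q_in, rep(0.25, 4), tolerance = 0.5)
  expect_equal(sum(qp > 0), 4L)
})

test_that("subdomain growth logs records, freezes the outside, is local", {
  bl <- make_baseline()
  res <- grow_subdomain(bl$tree, bl$part, 2L, 15L, stage_config(N = 0L),
                        seed = 9)
  expect_equal(n_terminals(res$tree), n_terminals(bl$tree) + 15L)
  expect_equal(nrow(res$records), 15L)
  expect_identical(res$records$seq, 1:15)
  expect_identical(unique(res$records$subdomain), 2L)
  # N_i = 0: tree unchanged topologically, no records
  r0 <- grow_subdomain(bl$tree, bl$part, 1L, 0L, stage_config(N = 0L),
                       seed = 9)
  expect_equal(nrow(r0$records), 0L)
  expect_identical(r0$tree$id, bl$tree$id)
  # all new distal points lie inside the subdomain
  new_ids <- setdiff(res$tree$id, bl$tree$id)
  term_new <- intersect(new_ids, terminal_ids(res$tree))
  xd_new <- res$tree$xd[match(term_new, res$tree$id), , drop = FALSE]
  expect_true(all(label_point(bl$part, xd_new) == 2L))
  # frozen outside terminals kept their baseline outflow
  fc <- subdomain_flow_conditions(bl$tree, bl$part, 2L)
  surv <- intersect(as.integer(names(fc$frozen)), res$tree$id)
  expect_equal(res$tree$Q[match(surv, res$tree$id)],
               unname(fc$frozen[as.character(surv)]), tolerance = 1e-15)
  # growth in one subdomain is independent of growth in another
  resA <- grow_subdomain(bl$tree, bl$part, 1L, 10L, stage_config(N = 0L),
                         seed = 9)
  resB <- grow_subdomain(bl$tree, bl$part, 3L, 10L, stage_config(N = 0L),
                         seed = 9)
  resA2 <- grow_subdomain(bl$tree, bl$part, 1L, 10L, stage_config(N = 0L),
                          seed = 9)
  expect_identical(resA$records, resA2$records)
  expect_false(identical(resA$records, resB$records))
})

test_that("records resolve against the baseline in their own subdomain", {
  bl <- make_baseline()
  res <- grow_subdomain(bl$tree, bl$part, 3L, 12L, stage_config(N = 0L),
                        seed = 4)
  # every record's parent midpoint (at insertion time) lies in subdomain 3,
  # or the parent was created by this subdomain's own growth
  mids <- cbind((res$records$pp_x + res$records$pd_x) / 2,
                (res$records$pp_y + res$records$pd_y) / 2,
                (res$records$pp_z + res$records$pd_z) / 2)
  expect_true(all(label_point(bl$part, mids) == 3L))
})

test_that("merge replays records exactly and restores the invariants", {
  bl <- make_baseline(n_term = 30L, seed = 8)
  st <- stage_config(N = 0L)
  subs <- lapply(1:4, function(i)
    grow_subdomain(bl$tree, bl$part, i, 8L, st, seed = 8))
  merged <- merge_trees(bl$tree, lapply(subs, `[[`, "records"))
  # merge-count law
  expect_equal(n_terminals(merged), 30L + 4L * 8L)
  expect_equal(n_segments(merged), 2L * (30L + 32L) - 1L)
  validate_tree(merged, hemodynamic = TRUE)
  # merged topology contains each subdomain's coordinates exactly
  for (i in 1:4) {
    ti <- subs[[i]]$tree
    keys_i <- paste(ti$xd[, 1], ti$xd[, 2], ti$xd[, 3])
    keys_m <- paste(merged$xd[, 1], merged$xd[, 2], merged$xd[, 3])
    expect_true(all(keys_i %in% keys_m))
  }
  # flows sum to Q_in across terminals
  q <- merged$Q[match(terminal_ids(merged), merged$id)]
  expect_equal(sum(q), merged$Q_in, tolerance = 1e-12)
  # zero records: identity after a rescaling pass
  m0 <- merge_trees(bl$tree, list())
  expect_identical(m0$id, bl$tree$id)
  expect_equal(m0$r, bl$tree$r, tolerance = 1e-12)
  # corrupted record errors with its position
  rec <- subs[[1]]$records
  rec$pp_x[3] <- rec$pp_x[3] + 1e-7
  expect_error(merge_trees(bl$tree, list(rec)), "corrupted record")
})

test_that("replay order across subdomains cannot change the result", {
  bl <- make_baseline(n_term = 25L, seed = 12)
  st <- stage_config(N = 0L)
  subs <- lapply(1:4, function(i)
    grow_subdomain(bl$tree, bl$part, i, 6L, st, seed = 12))
  recs <- lapply(subs, `[[`, "records")
  m1 <- merge_trees(bl$tree, recs, tags = sprintf("s%d", 1:4))
  m2 <- merge_trees(bl$tree, recs[c(3, 1, 4, 2)],
                    tags = sprintf("s%d", c(3, 1, 4, 2)))
  # same geometry and same radii regardless of list order
  k1 <- order(paste(m1$xd[, 1], m1$xd[, 2], m1$xd[, 3]))
  k2 <- order(paste(m2$xd[, 1], m2$xd[, 2], m2$xd[, 3]))
  expect_identical(m1$xd[k1, ], m2$xd[k2, ])
  expect_equal(m1$r[k1], m2$r[k2], tolerance = 1e-12)
})

test_that("pipeline: degenerate partition equals two-phase sequential growth", {
  dom <- fig_box()
  part1 <- partition_axis_aligned(dom, c(1L, 1L, 1L))
  t0 <- default_inlet_tree()
  st <- stage_config(N = 0L)
  res <- pdcco_pipeline(t0, dom, part1, N_base = 20L, N_i = 10L, stage = st,
                        seed = 6)
  expect_equal(n_terminals(res$merged), 30L)
  expect_equal(n_terminals(res$baseline), 20L)
  validate_tree(res$merged, hemodynamic = TRUE)
})

test_that("pipeline: serial and concurrent execution are bit-identical", {
  dom <- fig_box()
  part <- partition_axis_aligned(dom, c(4L, 1L, 1L))
  t0 <- default_inlet_tree()
  st <- stage_config(N = 0L)
  serial <- pdcco_pipeline(t0, dom, part, N_base = 25L, N_i = rep(8L, 4),
                           stage = st, seed = 10, cores = 1L)
  conc <- pdcco_pipeline(t0, dom, part, N_base = 25L, N_i = rep(8L, 4),
                         stage = st, seed = 10, cores = 2L)
  expect_identical(serial$merged, conc$merged)
  expect_identical(serial$records, conc$records)
})
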