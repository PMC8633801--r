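# Desk-scale experiment harness: scaled-down versions of the standard
# comparison studies between sequentially and partition-grown networks.
# Every run is fully determined by (overrides, seed); all seeds are logged
# in the returned bundle.

# shared machinery: for one seed, grow a baseline, continue it sequentially
# to N_total (the sequential instance) and, from the same baseline, run the
# partitioned growth to the same N_total (the parallel instance)
.paired_instance <- function(domain, partition, inlet, N_base, N_total,
                             stage, seed) {
  t0 <- vascular_tree(inlet$x_prox, inlet$x_dist, r0 = inlet$r0,
                      Q_in = inlet$Q_in, gamma = stage$gamma)
  stb <- stage
  stb$N <- as.integer(N_base)
  stb$tag <- "baseline"
  baseline <- grow(t0, domain, stb, seed = seed, stream = 0L)
  # sequential continuation
  sts <- stage
  sts$N <- as.integer(N_total - N_base)
  sts$tag <- "sequential"
  dcco <- grow(baseline, domain, sts, seed = seed, stream = 100L)
  # partitioned continuation from the same baseline
  npart <- length(partition$subdomains)
  N_i <- split_quotient_remainder(N_total - N_base, npart)
  subs <- lapply(seq_len(npart), function(i) {
    sti <- stage
    sti$tag <- sprintf("sub-%d", i)
    grow_subdomain(baseline, partition, i, N_i[i], sti, seed = seed)
  })
  merged <- merge_trees(baseline, lapply(subs, `[[`, "records"),
                        model = stage$viscosity)
  list(baseline = baseline, dcco = dcco, pdcco = merged, seed = seed)
}

.default_inlet <- function(domain) {
  lo <- domain$lo; hi <- domain$hi
  mid <- (lo + hi) / 2
  x_prox <- c(lo[1], mid[2], mid[3])
  x_dist <- c(lo[1] + 0.1 * (hi[1] - lo[1]), mid[2], mid[3])
  list(x_prox = x_prox, x_dist = x_dist, r0 = 0.075, Q_in = 0.002)
}

#' Run a named desk-scale experiment
#'
#' Scaled-down versions of the standard comparison protocols.  Available
#' names:
#' \describe{
#'   \item{`baseline-sensitivity`}{paired sequential/parallel instances at a
#'     fixed total terminal count for several baseline sizes; reports the
#'     relative intravascular volume error per baseline size.}
#'   \item{`aspect-ratio`}{the same pairing on `4L x 1 x 1` boxes split into
#'     four `L x 1 x 1` cells, with inlet data rescaled by the allometric
#'     laws `Q ~ V`, `r0 ~ V^{3/8}`.}
#'   \item{`multi-inlet-sweep`}{baseline networks grown from a four-inlet
#'     external seed in a side-2 cube for a list of cost coefficient tuples
#'     `(c_v, c_p, c_d)`; reports the flow fraction carried by each inlet
#'     branch.}
#'   \item{`scalability`}{one partitioned run on an `n x n` partition of a
#'     parallelepipedal domain; reports counts, volume and timing by phase.}
#' }
#'
#' @param name experiment name.
#' @param overrides named list overriding the defaults listed by
#'   `experiment_defaults(name)` (instance counts, terminal counts, seeds,
#'   L values, coefficient list, ...).
#' @return a result bundle (list) containing the summary table(s), the
#'   resolved settings and all seeds used.
#' @export
experiment_harness <- function(name = c("baseline-sensitivity", "aspect-ratio",
                                        "multi-inlet-sweep", "scalability"),
                               overrides = list()) {
  name <- match.arg(name)
  cfg <- utils::modifyList(experiment_defaults(name), overrides)
  switch(name,
         "baseline-sensitivity" = .exp_baseline_sensitivity(cfg),
         "aspect-ratio" = .exp_aspect_ratio(cfg),
         "multi-inlet-sweep" = .exp_multi_inlet(cfg),
         "scalability" = .exp_scalability(cfg))
}

#' Default settings of a named experiment
#' @param name experiment name as in [experiment_harness()].
#' @return named list of defaults.
#' @export
experiment_defaults <- function(name) {
  switch(name,
    "baseline-sensitivity" = list(
      N_total = 500L, N_base = c(125L, 250L), instances = 3L, seeds = 1:3,
      box = c(4, 1, 1), counts = c(4L, 1L, 1L),
      stage = stage_config(N = 0L), inlet = NULL),
    "aspect-ratio" = list(
      L = c(0.5, 1), N_total = 400L, N_base = 200L, seeds = 1:2,
      Q_ref = 0.002, r_ref = 0.075, V_ref = 4,
      stage = stage_config(N = 0L)),
    "multi-inlet-sweep" = list(
      coefficients = list(c(1, 0, 0), c(0.5, 0.4, 0.1)),
      N_base = 50L, seeds = 1L, gamma = 3,
      V_ref = 8, l_ref = 2, r_ref = 0.1),
    "scalability" = list(
      box = c(5, 5, 2.3), counts = c(4L, 4L, 1L), N_total = 5000L,
      N_base = 1000L, seed = 1L, Q_in = 0.002, r0 = 0.075,
      stage = stage_config(N = 0L)),
    stop("unknown experiment: ", name))
}

.exp_baseline_sensitivity <- function(cfg) {
  domain <- box_domain(c(0, 0, 0), cfg$box)
  partition <- partition_axis_aligned(domain, cfg$counts)
  inlet <- if (is.null(cfg$inlet)) .default_inlet(domain) else cfg$inlet
  seeds <- cfg$seeds[seq_len(cfg$instances)]
  rows <- list()
  for (nb in cfg$N_base) {
    runs <- lapply(seeds, function(s)
      .paired_instance(domain, partition, inlet, nb, cfg$N_total, cfg$stage, s))
    vd <- vapply(runs, function(r) intravascular_volume(r$dcco), 1.0)
    vp <- vapply(runs, function(r) intravascular_volume(r$pdcco), 1.0)
    err <- relative_volume_error(vp, vd)
    rows[[length(rows) + 1L]] <- data.frame(
      N_base = nb, seed = seeds, V_dcco = vd, V_pdcco = vp,
      rel_vol_error = err$errors)
  }
  table <- do.call(rbind, rows)
  list(name = "baseline-sensitivity", table = table,
       median_abs_error = abs(median(table$rel_vol_error)),
       settings = cfg, seeds = seeds)
}

.exp_aspect_ratio <- function(cfg) {
  rows <- list()
  for (L in cfg$L) {
    domain <- box_domain(c(0, 0, 0), c(4 * L, 1, 1))
    partition <- partition_axis_aligned(domain, c(4L, 1L, 1L))
    sc <- allometric_inlet_scaling(domain_volume(domain), cfg$Q_ref,
                                   cfg$r_ref, cfg$V_ref)
    inlet <- list(x_prox = c(0, 0.5, 0.5), x_dist = c(L / 10, 0.5, 0.5),
                  r0 = sc$r0, Q_in = sc$Q)
    for (s in cfg$seeds) {
      run <- .paired_instance(domain, partition, inlet, cfg$N_base,
                              cfg$N_total, cfg$stage, s)
      rows[[length(rows) + 1L]] <- data.frame(
        L = L, aspect_ratio = L, seed = s,
        V_dcco = intravascular_volume(run$dcco),
        V_pdcco = intravascular_volume(run$pdcco))
    }
  }
  table <- do.call(rbind, rows)
  table$rel_vol_error <- NA_real_
  for (L in unique(table$L)) {
    i <- table$L == L
    m <- mean(table$V_dcco[i])
    table$rel_vol_error[i] <- (table$V_pdcco[i] - m) / m
  }
  list(name = "aspect-ratio", table = table, settings = cfg)
}

#' Synthetic four-inlet external seed network for a cube domain
#'
#' A handcrafted seven-segment binary tree standing in for an external supply
#' network (the reference geometry is not published): the root and two feeder
#' hubs sit above the cube, and four terminal branches descend into it,
#' each crossing the boundary exactly once.  Only these four crossing
#' branches are flagged as eligible growth parents, so the domain keeps
#' exactly four inlets while it is vascularized (use `in_check = "new"`).
#'
#' @param side cube side length (the cube is centred at the origin).
#' @param r0 root radius (cm).
#' @param Q_in inlet flow (cm^3/s).
#' @param gamma branching exponent.
#' @return a `vascular_tree` with 4 terminals, flows and radii assigned.
#' @export
four_inlet_seed <- function(side = 2, r0 = 0.1, Q_in = 0.002, gamma = 3) {
  h <- side / 2
  xp <- rbind(c(0, 0, 2.4), c(0, 0, 2.0), c(0, 0, 2.0),
              c(1.3, 0, 1.2), c(1.3, 0, 1.2),
              c(-1.3, 0, 1.2), c(-1.3, 0, 1.2)) * h
  xd <- rbind(c(0, 0, 2.0), c(1.3, 0, 1.2), c(-1.3, 0, 1.2),
              c(0.85, 0, 0), c(0, 0.85, 0),
              c(-0.85, 0, 0), c(0, -0.85, 0)) * h
  tr <- new_vascular_tree(list(
    id = 1:7,
    parent = c(NA, 1L, 1L, 2L, 2L, 3L, 3L),
    c1 = c(2L, 4L, 6L, NA, NA, NA, NA),
    c2 = c(3L, 5L, 7L, NA, NA, NA, NA),
    xp = xp, xd = xd,
    r = r0 * c(1, 0.8, 0.8, 0.65, 0.65, 0.65, 0.65),
    beta = rep(1, 7), Q = rep(Q_in, 7), mu = rep(0.036, 7),
    qfix = rep(NaN, 7), nterm = c(4L, 2L, 2L, 1L, 1L, 1L, 1L),
    stage = rep("seed", 7),
    # only the four boundary-crossing branches may be split during growth
    allowed = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    root = 1L, gamma = gamma, Q_in = Q_in, r0 = r0, next_id = 8L))
  rescale_radii(assign_terminal_flows(tr))
}

.exp_multi_inlet <- function(cfg) {
  domain <- box_domain(c(-1, -1, -1), c(1, 1, 1))
  rows <- list()
  for (k in seq_along(cfg$coefficients)) {
    cv <- cfg$coefficients[[k]]
    F <- cost_functional("sprouting", c_v = cv[1], c_p = cv[2], c_d = cv[3],
                         V_ref = cfg$V_ref, l_ref = cfg$l_ref,
                         r_ref = cfg$r_ref, gamma = cfg$gamma)
    st <- stage_config(N = cfg$N_base, cost = F, in_check = "new",
                       tag = sprintf("sweep-%d", k))
    for (s in cfg$seeds) {
      seedling <- four_inlet_seed()
      tr <- grow(seedling, domain, st, seed = s)
      # inlet branches = the four vessels that were terminals of the seed,
      # identified as the segments crossing each face at generation >= 2
      inlets <- .inlet_branch_flows(tr, domain)
      rows[[length(rows) + 1L]] <- data.frame(
        combo = k, c_v = cv[1], c_p = cv[2], c_d = cv[3], seed = s,
        inlet = seq_along(inlets), flow_fraction = inlets / tr$Q_in)
    }
  }
  table <- do.call(rbind, rows)
  sdev <- stats::aggregate(flow_fraction ~ combo, table, sd)
  names(sdev)[2] <- "flow_fraction_sd"
  list(name = "multi-inlet-sweep", table = table, balance = sdev,
       settings = cfg)
}

# flows carried into the domain: one boundary-crossing segment per inlet
# branch (outside vessels are not eligible parents, and every new terminal
# lies fully inside, so each root-to-terminal path crosses exactly once)
.inlet_branch_flows <- function(tree, domain) {
  pin <- contains(domain, tree$xp)
  din <- contains(domain, tree$xd)
  idx <- which(!pin & din)
  sort(tree$Q[idx], decreasing = TRUE)
}

.exp_scalability <- function(cfg) {
  domain <- box_domain(c(0, 0, 0), cfg$box)
  partition <- partition_axis_aligned(domain, cfg$counts)
  inlet <- .default_inlet(domain)
  inlet$r0 <- cfg$r0; inlet$Q_in <- cfg$Q_in
  t0 <- vascular_tree(inlet$x_prox, inlet$x_dist, r0 = inlet$r0,
                      Q_in = inlet$Q_in, gamma = cfg$stage$gamma)
  st <- cfg$stage
  st$N <- as.integer(cfg$N_base) - n_terminals(t0) # N_base = target count
  st$tag <- "baseline"
  tb <- system.time(baseline <- grow(t0, domain, st, seed = cfg$seed,
                                     stream = 0L))["elapsed"]
  npart <- length(partition$subdomains)
  N_i <- split_quotient_remainder(cfg$N_total - cfg$N_base, npart)
  tsub <- numeric(npart)
  subs <- vector("list", npart)
  for (i in seq_len(npart)) {
    sti <- cfg$stage
    sti$tag <- sprintf("sub-%d", i)
    tsub[i] <- system.time(
      subs[[i]] <- grow_subdomain(baseline, partition, i, N_i[i], sti,
                                  seed = cfg$seed))["elapsed"]
  }
  tm <- system.time(
    merged <- merge_trees(baseline, lapply(subs, `[[`, "records"),
                          model = cfg$stage$viscosity))["elapsed"]
  list(name = "scalability",
       table = data.frame(
         phase = c("baseline", "subdomains_mean", "subdomains_sd", "merge"),
         seconds = c(tb, mean(tsub), sd(tsub), tm)),
       n_terminals = n_terminals(merged),
       volume = intravascular_volume(merged),
       merged = merged, settings = cfg)
}

#' Sequential-growth timing curve
#'
#' Times the sequential addition of `N` terminals for each requested size and
#' fits `log(time) ~ log(N)`; the slope estimates the empirical order of the
#' sequential construction cost.
#'
#' @param N_seq integer vector of terminal counts.
#' @param domain `perfusion_domain` (a unit-volume box by default).
#' @param stage a [stage_config()].
#' @param seed seed.
#' @return list with `table` (N, seconds) and `slope`.
#' @export
growth_cost_scaling <- function(N_seq = c(250L, 500L, 1000L, 2000L),
                                domain = box_domain(c(0, 0, 0), c(4, 1, 1)),
                                stage = stage_config(N = 0L), seed = 1L) {
  inlet <- .default_inlet(domain)
  secs <- vapply(N_seq, function(N) {
    st <- stage
    st$N <- as.integer(N)
    t0 <- vascular_tree(inlet$x_prox, inlet$x_dist, r0 = inlet$r0,
                        Q_in = inlet$Q_in, gamma = stage$gamma)
    as.numeric(system.time(grow(t0, domain, st, seed = seed))["elapsed"])
  }, 1.0)
  fit <- lm(log(secs) ~ log(as.numeric(N_seq)))
  list(table = data.frame(N = N_seq, seconds = secs),
       slope = unname(coef(fit)[2]))
}
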