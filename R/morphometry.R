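# Morphometric and functional characterization: generation profiles,
# Strahler ordering, connectivity, volumes.

#' Total intravascular volume (cm^3)
#'
#' `sum(pi l_i r_i^2)` over all segments.
#'
#' @param tree a `vascular_tree`.
#' @return volume in cm^3.
#' @export
intravascular_volume <- function(tree) {
  sum(pi * segment_lengths(tree) * tree$r^2)
}

#' Relative intravascular volume error
#'
#' The agreement metric between partition-grown and sequentially grown
#' networks: each parallel instance's volume minus the mean sequential
#' volume, normalized by that mean,
#' `e_k = (V_parallel,k - mean(V_seq)) / mean(V_seq)`.
#'
#' @param pdcco_volumes volumes of the partition-grown instances (cm^3).
#' @param dcco_volumes volumes of the sequentially grown instances (cm^3).
#' @return list with `errors` (signed, per parallel instance), `median`,
#'   `mean`, and `mean_abs`.
#' @export
relative_volume_error <- function(pdcco_volumes, dcco_volumes) {
  if (length(dcco_volumes) == 0) stop("need at least one sequential volume")
  m <- mean(dcco_volumes)
  if (m == 0) stop("mean sequential volume is zero")
  e <- (pdcco_volumes - m) / m
  list(errors = e, median = median(e), mean = mean(e),
       mean_abs = mean(abs(e)))
}

#' Strahler orders of all vessels
#'
#' Leaf-up ordering: terminals have order 0; a parent of daughters with
#' orders `(a, b)` has order `max(a, b)` when they differ and `a + 1` when
#' equal.  (When reporting, the synthetic inlet feeding the root may be
#' labelled order -1; the computation itself never uses that convention.)
#'
#' @param tree a `vascular_tree`.
#' @return integer vector of orders, in table order.
#' @export
strahler_orders <- function(tree) {
  n <- n_segments(tree)
  ord <- integer(n)
  i1 <- match(tree$c1, tree$id)
  i2 <- match(tree$c2, tree$id)
  for (i in order(generation_of(tree), decreasing = TRUE)) {
    if (is.na(i1[i])) {
      ord[i] <- 0L
    } else {
      a <- ord[i1[i]]; b <- ord[i2[i]]
      ord[i] <- if (a == b) a + 1L else max(a, b)
    }
  }
  ord
}

#' Connectivity matrix over Strahler orders
#'
#' `C[p, c]` counts parent-child vessel pairs whose Strahler orders are
#' `p` and `c` (labels give the orders); the entries sum to the number of
#' parent-child edges, `n_segments - 1`.
#'
#' @param tree a `vascular_tree`.
#' @return integer matrix with dimnames giving the orders.
#' @export
connectivity_matrix <- function(tree) {
  ord <- strahler_orders(tree)
  pidx <- match(tree$parent, tree$id)
  keep <- !is.na(pidx)
  po <- ord[pidx[keep]]
  co <- ord[keep]
  lv <- 0:max(ord)
  C <- table(factor(po, levels = lv), factor(co, levels = lv))
  m <- matrix(as.integer(C), nrow = length(lv),
              dimnames = list(parent = lv, child = lv))
  m
}

#' Per-vessel subtended intravascular volume
#'
#' The total volume of the subtree rooted at each vessel (the vessel
#' included), in cm^3.
#'
#' @param tree a `vascular_tree`.
#' @return numeric vector in table order.
#' @export
subtended_volume <- function(tree) {
  v <- pi * segment_lengths(tree) * tree$r^2
  i1 <- match(tree$c1, tree$id)
  i2 <- match(tree$c2, tree$id)
  out <- numeric(n_segments(tree))
  for (i in order(generation_of(tree), decreasing = TRUE)) {
    out[i] <- v[i] + (if (is.na(i1[i])) 0 else out[i1[i]] + out[i2[i]])
  }
  out
}

# box-plot style summary with whiskers at 1.5 IQR (the standard convention)
.boxstats <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lw <- min(x[x >= q[1] - 1.5 * iqr])
  uw <- max(x[x <= q[3] + 1.5 * iqr])
  c(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = lw, whisker_high = uw, mean = mean(x))
}

#' Generation-wise profile of a per-vessel quantity
#'
#' Gathers all vessels of each generation and summarizes the quantity with
#' box-plot statistics (median, quartiles, whiskers at 1.5 IQR).
#'
#' @param tree a `vascular_tree`.
#' @param values numeric vector, one value per vessel in table order (e.g.
#'   radii, lengths, or pressures from a [solve_pressures()] solution).
#' @return data.frame with one row per generation.
#' @export
generation_profile <- function(tree, values) {
  gen <- generation_of(tree)
  stopifnot(length(values) == length(gen))
  gens <- sort(unique(gen))
  out <- do.call(rbind, lapply(gens, function(g) .boxstats(values[gen == g])))
  data.frame(generation = gens, out, row.names = NULL)
}

#' Full morphometric/functional profile set of a solved tree
#'
#' Computes the standard comparison summaries: generation profiles of
#' radius, length, aspect ratio (length/diameter) and distal pressure;
#' the radius-length joint histogram; lumen area, vessel count, mean
#' pressure and mean flow per Strahler order; and the per-vessel subtended
#' volume against radius.
#'
#' @param tree a `vascular_tree`.
#' @param solution a [solve_pressures()] result for `tree` (computed if
#'   missing).
#' @param rl_breaks number of histogram bins per axis for the radius-length
#'   distribution.
#' @return a list of data.frames: `radius`, `length`, `aspect`, `pressure`
#'   (generation profiles), `radius_length` (binned counts), `strahler`
#'   (per-order summaries), `subtended` (per-vessel radius and subtended
#'   volume).
#' @export
profiles <- function(tree, solution = solve_pressures(tree), rl_breaks = 20L) {
  len <- segment_lengths(tree)
  stopifnot(identical(solution$id, tree$id))
  res <- list(
    radius = generation_profile(tree, tree$r),
    length = generation_profile(tree, len),
    aspect = generation_profile(tree, len / (2 * tree$r)),
    pressure = generation_profile(tree, solution$p_dist))
  rb <- seq(min(tree$r), max(tree$r), length.out = rl_breaks + 1L)
  lb <- seq(min(len), max(len), length.out = rl_breaks + 1L)
  ri <- cut(tree$r, rb, include.lowest = TRUE)
  li <- cut(len, lb, include.lowest = TRUE)
  h <- as.data.frame(table(radius_bin = ri, length_bin = li),
                     stringsAsFactors = FALSE)
  names(h)[3] <- "count"
  res$radius_length <- h
  ord <- strahler_orders(tree)
  sidx <- split(seq_along(ord), ord)
  res$strahler <- data.frame(
    order = as.integer(names(sidx)),
    n = vapply(sidx, length, 1L),
    lumen_area = vapply(sidx, function(i) sum(pi * tree$r[i]^2), 1.0),
    mean_pressure = vapply(sidx, function(i) mean(solution$p_dist[i]), 1.0),
    mean_flow = vapply(sidx, function(i) mean(tree$Q[i]), 1.0),
    row.names = NULL)
  res$subtended <- data.frame(id = tree$id, r = tree$r,
                              subtended_volume = subtended_volume(tree))
  res
}
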