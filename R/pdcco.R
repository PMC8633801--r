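# Partitioned (parallel) constructive growth: baseline tree, independent
# subdomain refinement with insertion-record logging, and the consistent
# merge with deferred radius scaling.

#' Baseline vessels eligible as parents inside a subdomain
#'
#' A baseline vessel belongs to a subdomain's parent set exactly when its
#' midpoint lies inside that subdomain; because the cells are disjoint and
#' the labelling is half-open, a vessel can bifurcate in at most one
#' subdomain, which is what makes the merge consistent.
#'
#' @param tree the baseline `vascular_tree`.
#' @param partition a `domain_partition`.
#' @param index 1-based subdomain index.
#' @return integer vector of vessel ids; errors if empty (the subdomain
#'   cannot be grown).
#' @export
partition_parents <- function(tree, partition, index) {
  lab <- label_point(partition, segment_midpoints(tree))
  ids <- tree$id[!is.na(lab) & lab == index]
  if (length(ids) == 0)
    stop("subdomain ", index,
         " contains no baseline vessel midpoint; it cannot be grown")
  ids
}

#' Terminal flow conditions for subdomain growth
#'
#' Terminals outside the subdomain's parent set keep their baseline outflow
#' frozen; the remaining flow `Q_part = Q_in - sum(frozen)` is split
#' homogeneously among the terminals inside (their count grows as terminals
#' are inserted).  Total inlet flow is conserved at every step.
#'
#' @param tree the baseline `vascular_tree` with flows assigned.
#' @param partition a `domain_partition`.
#' @param index subdomain index.
#' @return list with `frozen` (named numeric vector: ids -> fixed outflow),
#'   `free_ids` (terminals inside), and `Q_part`.
#' @export
subdomain_flow_conditions <- function(tree, partition, index) {
  vpart <- partition_parents(tree, partition, index)
  term <- terminal_ids(tree)
  frozen_ids <- setdiff(term, vpart)
  free_ids <- intersect(term, vpart)
  idx <- match(frozen_ids, tree$id)
  frozen <- tree$Q[idx]
  names(frozen) <- frozen_ids
  Q_part <- tree$Q_in - sum(frozen)
  if (length(free_ids) > 0 && Q_part <= 0)
    stop("remaining subdomain flow Q_part is non-positive")
  list(frozen = frozen, free_ids = free_ids, Q_part = Q_part)
}

#' Grow one subdomain from the shared baseline tree
#'
#' Candidate points are sampled inside the subdomain; only baseline vessels
#' of the subdomain's parent set (plus vessels created here) may be split,
#' while the whole network still participates in collision checks.  Every
#' accepted insertion is logged, in order, as a record
#' `(x_new, x_bif, parent x_p, parent x_d)` for later replay.  Growth is
#' independent of any other subdomain (no shared mutable state), so
#' subdomains may be processed concurrently or serially with identical
#' results.
#'
#' @param tree the baseline `vascular_tree`.
#' @param partition a `domain_partition` of the perfusion domain.
#' @param index subdomain index.
#' @param N_i terminals to add in this subdomain.
#' @param stage a [stage_config()] (its `N` is ignored in favour of `N_i`).
#' @param seed global seed; the subdomain stream is derived from
#'   `(seed, index)`.
#' @return list with `tree` (the locally grown tree `T_i`) and `records`
#'   (data.frame of insertion records with `seq` and `subdomain` columns).
#' @export
grow_subdomain <- function(tree, partition, index, N_i, stage,
                           seed = partition$parent$seed) {
  vpart <- partition_parents(tree, partition, index)
  cond <- subdomain_flow_conditions(tree, partition, index)
  tree <- assign_terminal_flows(tree, fixed = cond$frozen)
  tree$allowed <- tree$id %in% vpart
  st <- stage
  st$N <- as.integer(N_i)
  out <- grow(tree, partition$parent, st, seed = seed, stream = index,
              sample_domain = partition$subdomains[[index]],
              keep_records = TRUE)
  rec <- attr(out, "records")
  rec$subdomain <- rep(index, nrow(rec))
  attr(out, "records") <- NULL
  out$allowed <- rep(TRUE, n_segments(out))
  list(tree = out, records = rec)
}

#' Merge subdomain growth records into the baseline tree
#'
#' Starting from the baseline, the record lists are replayed in subdomain
#' order (each list in its own sequential order); each record's parent is
#' resolved by the exact full-precision coordinate pair `(x_p, x_d)` in a
#' lookup table maintained under splits.  Radii are NOT rescaled during
#' replay: after all insertions the terminal outflows are redistributed
#' homogeneously and one global viscosity/radius fixed point restores the
#' branching power law and the equal-terminal-pressure closure.
#'
#' @param baseline the baseline `vascular_tree` the records were generated
#'   from.
#' @param record_lists list of record data.frames (one per subdomain, as
#'   returned by [grow_subdomain()]).
#' @param model [viscosity_model()] for the final pass.
#' @param tol,max_iter fixed-point controls.
#' @param tags stage tags for replayed vessels (one per list; defaults to
#'   `"merge-<i>"`).
#' @return the merged `vascular_tree` after the final haemodynamic pass.
#' @export
merge_trees <- function(baseline, record_lists,
                        model = viscosity_model("constant"),
                        tol = 1e-6, max_iter = 100L, tags = NULL) {
  if (is.null(tags))
    tags <- sprintf("merge-%d", seq_along(record_lists))
  ct <- .tree_to_cpp(baseline)
  levels <- attr(ct, "stage_levels")
  newtags <- setdiff(tags, levels)
  levels <- c(levels, newtags)
  ct$stage_code <- match(baseline$stage, levels)
  mats <- lapply(record_lists, function(r) {
    as.matrix(r[, c("xn_x", "xn_y", "xn_z", "xb_x", "xb_y", "xb_z",
                    "pp_x", "pp_y", "pp_z", "pd_x", "pd_y", "pd_z")])
  })
  merged <- cpp_merge(ct, mats, match(tags, levels))
  merged <- .tree_from_cpp(merged, levels)
  merged <- assign_terminal_flows(merged) # homogeneous outflows
  fixed_point_viscosity_radii(merged, model, tol, max_iter)$tree
}

#' Expected merged terminal count
#'
#' The merge-count law: the merged network has `N_base + sum(N_i)` terminal
#' segments.
#'
#' @param N_base baseline terminal count.
#' @param N_i vector of per-subdomain additions.
#' @return integer total.
#' @export
#' @examples
#' merged_terminal_count(500, rep(200, 4)) # 1300
merged_terminal_count <- function(N_base, N_i) {
  as.integer(N_base + sum(N_i))
}

#' Full partitioned-growth pipeline
#'
#' Three phases: (i) sequential growth of a baseline tree with `N_base`
#' terminals over the whole domain; (ii) independent growth of `N_i`
#' terminals inside each partition cell from the shared baseline (serially
#' or concurrently -- the results are identical by construction); (iii)
#' record replay onto the baseline and one global haemodynamic pass.
#'
#' @param tree initial `vascular_tree` (typically a single root segment).
#' @param domain the perfusion domain.
#' @param partition a `domain_partition` of it.
#' @param N_base terminal count of the baseline tree: the initial tree is
#'   grown until it has `N_base` terminals, so the merged network has exactly
#'   `N_base + sum(N_i)` terminals (the merge-count law).
#' @param N_i per-subdomain additions: a vector of length `N_part`, or a
#'   single total to split by quotient/remainder.
#' @param stage [stage_config()] template used for all phases.
#' @param seed global seed; the baseline uses stream 0 and subdomain `i`
#'   stream `i`.
#' @param cores subdomain growths are executed with
#'   [parallel::mclapply()] when `cores > 1`.
#' @return list with `baseline`, `subgrowths` (list of
#'   [grow_subdomain()] results), `records` (combined data.frame) and
#'   `merged`.
#' @export
pdcco_pipeline <- function(tree, domain, partition, N_base, N_i, stage,
                           seed = domain$seed, cores = 1L) {
  npart <- length(partition$subdomains)
  if (length(N_i) == 1 && npart > 1)
    N_i <- split_quotient_remainder(N_i, npart)
  stopifnot(length(N_i) == npart)
  if (N_base < n_terminals(tree))
    stop("N_base is below the initial tree's terminal count")
  st <- stage
  st$N <- as.integer(N_base) - n_terminals(tree)
  st$tag <- "baseline"
  baseline <- grow(tree, domain, st, seed = seed, stream = 0L)
  grow_one <- function(i) {
    sti <- stage
    sti$tag <- sprintf("sub-%d", i)
    grow_subdomain(baseline, partition, i, N_i[i], sti, seed = seed)
  }
  subgrowths <- if (cores > 1L) {
    parallel::mclapply(seq_len(npart), grow_one, mc.cores = cores)
  } else {
    lapply(seq_len(npart), grow_one)
  }
  records <- lapply(subgrowths, `[[`, "records")
  merged <- merge_trees(baseline, records, model = stage$viscosity,
                        tags = sprintf("sub-%d", seq_len(npart)))
  list(baseline = baseline, subgrowths = subgrowths,
       records = do.call(rbind, records), merged = merged)
}
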