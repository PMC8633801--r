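# The vascular tree data model: a rooted strict-binary tree of rigid
# cylindrical segments.  Stored column-wise; topology edits and radius/flow
# bookkeeping are delegated to compiled code, this file owns the R-facing
# representation and validation.

.tree_fields <- c("id", "parent", "c1", "c2", "xp", "xd", "r", "beta", "Q",
                  "mu", "qfix", "nterm", "stage", "allowed")

new_vascular_tree <- function(lst) {
  stopifnot(all(.tree_fields %in% names(lst)))
  structure(lst, class = "vascular_tree")
}

#' Create a vascular tree from a single root segment
#'
#' @param x_prox,x_dist proximal and distal coordinates of the root vessel
#'   (cm); the proximal point is the network inlet where the reference (zero)
#'   pressure sits.
#' @param r0 root radius (cm); fixed input, propagated unchanged by radius
#'   rescaling.
#' @param Q_in inlet flow (cm^3/s).
#' @param gamma branching exponent of the power law
#'   `r_p^gamma = r_l^gamma + r_r^gamma`.
#' @param mu_cP initial effective viscosity (cP) before any viscosity update.
#' @param stage stage tag recorded on the root vessel.
#' @return a `vascular_tree` with one (terminal) segment.
#' @export
#' @examples
#' t0 <- vascular_tree(c(0, 0.5, 0.5), c(0.4, 0.5, 0.5), r0 = 0.1, Q_in = 1)
#' n_terminals(t0)
vascular_tree <- function(x_prox, x_dist, r0, Q_in, gamma = 3,
                          mu_cP = 3.6, stage = "root") {
  x_prox <- as.numeric(x_prox); x_dist <- as.numeric(x_dist)
  stopifnot(length(x_prox) == 3, length(x_dist) == 3, r0 > 0, Q_in > 0)
  if (sum((x_dist - x_prox)^2) == 0) stop("root segment has zero length")
  new_vascular_tree(list(
    id = 1L, parent = NA_integer_, c1 = NA_integer_, c2 = NA_integer_,
    xp = matrix(x_prox, 1, 3), xd = matrix(x_dist, 1, 3),
    r = r0, beta = 1, Q = Q_in, mu = mu_cP * 0.01,
    qfix = NaN, nterm = 1L, stage = stage, allowed = TRUE,
    root = 1L, gamma = gamma, Q_in = Q_in, r0 = r0, next_id = 2L))
}

# ---- compiled-code interchange ---------------------------------------------

.tree_to_cpp <- function(tree) {
  levels <- unique(tree$stage)
  lst <- unclass(tree)
  lst$stage_code <- match(tree$stage, levels)
  attr(lst, "stage_levels") <- levels
  lst
}

.tree_from_cpp <- function(ct, levels) {
  ct$stage <- levels[ct$stage_code]
  ct$stage_code <- NULL
  new_vascular_tree(ct)
}

# run a compiled op that maps tree -> tree
.tree_cpp_op <- function(tree, fn, ...) {
  ct <- .tree_to_cpp(tree)
  .tree_from_cpp(fn(ct, ...), attr(ct, "stage_levels"))
}

# ---- accessors --------------------------------------------------------------

#' Number of vessels / terminal vessels in a tree
#' @param tree a `vascular_tree`.
#' @return integer count.
#' @export
n_segments <- function(tree) length(tree$id)

#' @rdname n_segments
#' @export
n_terminals <- function(tree) sum(is.na(tree$c1) & is.na(tree$c2))

#' Ids of terminal vessels
#' @param tree a `vascular_tree`.
#' @return integer vector of vessel ids.
#' @export
terminal_ids <- function(tree) tree$id[is.na(tree$c1) & is.na(tree$c2)]

#' Segment lengths (cm)
#' @param tree a `vascular_tree`.
#' @return numeric vector in table order.
#' @export
segment_lengths <- function(tree) sqrt(rowSums((tree$xd - tree$xp)^2))

#' Segment midpoints
#' @param tree a `vascular_tree`.
#' @return (n x 3) matrix of midpoints (cm).
#' @export
segment_midpoints <- function(tree) (tree$xp + tree$xd) / 2

#' Vessel generation: number of bifurcations between a vessel and the root
#'
#' The root has generation 0; each crossed bifurcation adds one.  When a
#' vessel is split during growth, the proximal stub keeps the former vessel's
#' generation while the sibling and the new terminal sit one generation
#' deeper.
#'
#' @param tree a `vascular_tree`.
#' @param ids vessel ids to query; all vessels if `NULL`.
#' @return integer vector of generations.
#' @export
generation_of <- function(tree, ids = NULL) {
  gen <- cpp_generations(.tree_to_cpp(tree))
  if (is.null(ids)) return(gen)
  idx <- match(ids, tree$id)
  if (anyNA(idx)) stop("unknown vessel id")
  gen[idx]
}

#' Add a terminal vessel by splitting a parent segment
#'
#' The parent segment is replaced by a proximal stub ending at `x_bif` with
#' two children: the sibling (from `x_bif` to the old distal point, inheriting
#' the parent's children) and the new terminal (from `x_bif` to `x_new`).
#' Ids are never reused: the split vessel's id is retired and the stub,
#' sibling and terminal receive fresh consecutive ids.
#'
#' Flows and radii are NOT updated; call [assign_terminal_flows()] and
#' [rescale_radii()] (or [fixed_point_viscosity_radii()]) afterwards.
#'
#' @param tree a `vascular_tree`.
#' @param parent_id id of the vessel to split.
#' @param x_bif bifurcation point (cm), strictly between the parent endpoints.
#' @param x_new distal point of the new terminal (cm).
#' @param stage stage tag for the three new vessels; defaults to the split
#'   vessel's tag.
#' @return list with `tree` (updated), `stub_id`, `sibling_id`, `terminal_id`.
#' @export
add_terminal <- function(tree, parent_id, x_bif, x_new, stage = NULL) {
  idx <- match(parent_id, tree$id)
  if (is.na(idx)) stop("unknown parent vessel id: ", parent_id)
  tag <- if (is.null(stage)) tree$stage[idx] else stage
  ct <- .tree_to_cpp(tree)
  levels <- attr(ct, "stage_levels")
  if (!tag %in% levels) levels <- c(levels, tag)
  # re-encode with the (possibly) extended level set
  ct$stage_code <- match(tree$stage, levels)
  res <- cpp_add_terminal(ct, as.integer(parent_id), as.numeric(x_bif),
                          as.numeric(x_new), match(tag, levels))
  list(tree = .tree_from_cpp(res$tree, levels),
       stub_id = res$stub_id, sibling_id = res$sibling_id,
       terminal_id = res$terminal_id)
}

#' Assign terminal outflows and propagate flows bottom-up
#'
#' Under the uniform policy every terminal receives `Q_in / N_term`.  Under
#' the mixed policy the listed terminals keep an explicit fixed outflow and
#' the remaining flow `Q_part = Q_in - sum(fixed)` is split homogeneously
#' among the other terminals.  Internal flows are exact bottom-up sums, so
#' flow is conserved at every bifurcation by construction.
#'
#' @param tree a `vascular_tree`.
#' @param fixed optional named numeric vector: names are terminal vessel ids,
#'   values their fixed outflow (cm^3/s).  `NULL` means the uniform policy.
#' @return the updated tree.
#' @export
assign_terminal_flows <- function(tree, fixed = NULL) {
  tree$qfix <- rep(NaN, n_segments(tree))
  if (!is.null(fixed)) {
    ids <- as.integer(names(fixed))
    idx <- match(ids, tree$id)
    if (anyNA(idx)) stop("unknown terminal vessel id in fixed flows")
    if (any(!tree$id[idx] %in% terminal_ids(tree)))
      stop("fixed flows may only be placed on terminal vessels")
    tree$qfix[idx] <- as.numeric(fixed)
  }
  .tree_cpp_op(tree, cpp_assign_flows)
}

#' Rescale radii under the branching power law
#'
#' One pass of the reduced-resistance radius update: a leaf-to-root sweep
#' computes each subtree's Poiseuille resistance at unit subtree-root radius
#' and the daughter radius ratios that equalize the pressure drop across
#' sibling subtrees (equal-terminal-pressure closure), then a root-to-leaf
#' sweep propagates absolute radii from the fixed root radius `r0`.  After
#' the pass `r_p^gamma = r_l^gamma + r_r^gamma` holds at every bifurcation.
#' Viscosities are taken as currently stored; use
#' [fixed_point_viscosity_radii()] to couple them to the diameters.
#'
#' @param tree a `vascular_tree` with flows assigned.
#' @return the updated tree.
#' @export
rescale_radii <- function(tree) .tree_cpp_op(tree, cpp_rescale)

#' Validate the structural invariants of a tree
#'
#' Checks the strict-binary topology (0 or 2 children, one root, segment
#' count `2 N_term - 1`), positive radii and lengths, subtended-terminal
#' bookkeeping, and (optionally) flow conservation and the branching power
#' law.
#'
#' @param tree a `vascular_tree`.
#' @param hemodynamic also check flow conservation (relative tolerance
#'   1e-12) and the Murray-law residual (1e-10).
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_tree <- function(tree, hemodynamic = FALSE) {
  n <- n_segments(tree)
  nt <- n_terminals(tree)
  if (n != 2L * nt - 1L)
    stop("segment count ", n, " != 2 * ", nt, " - 1: not a strict binary tree")
  nchild <- (!is.na(tree$c1)) + (!is.na(tree$c2))
  if (any(nchild == 1L)) stop("vessel with exactly one child found")
  if (sum(is.na(tree$parent)) != 1L) stop("tree must have exactly one root")
  if (any(tree$r <= 0)) stop("non-positive radius")
  if (any(segment_lengths(tree) <= 0)) stop("zero-length segment")
  # recount subtended terminals by traversal
  recount <- .recount_nterm(tree)
  if (!identical(recount, tree$nterm))
    stop("subtended terminal counts inconsistent with topology")
  if (hemodynamic) {
    int <- which(!is.na(tree$c1))
    i1 <- match(tree$c1[int], tree$id); i2 <- match(tree$c2[int], tree$id)
    if (length(int)) {
      ferr <- abs(tree$Q[int] - tree$Q[i1] - tree$Q[i2]) / tree$Q[int]
      if (any(ferr > 1e-12)) stop("flow conservation violated")
      g <- tree$gamma
      merr <- abs(tree$r[int]^g - tree$r[i1]^g - tree$r[i2]^g) / tree$r[int]^g
      if (any(merr > 1e-10)) stop("branching power law violated")
    }
  }
  invisible(TRUE)
}

# independent recount of subtended terminals (used by validate and tests)
.recount_nterm <- function(tree) {
  n <- n_segments(tree)
  cnt <- integer(n)
  # process vessels deepest-first by repeated sweeps over a child-count table
  kids <- matrix(match(c(tree$c1, tree$c2), tree$id), ncol = 2)
  order <- order(cpp_generations(.tree_to_cpp(tree)), decreasing = TRUE)
  for (i in order) {
    cnt[i] <- if (is.na(kids[i, 1])) 1L else cnt[kids[i, 1]] + cnt[kids[i, 2]]
  }
  cnt
}

#' @export
print.vascular_tree <- function(x, ...) {
  cat(sprintf(
    "<vascular_tree: %d segments, %d terminals, gamma = %g, Q_in = %g cm^3/s, r0 = %g cm>\n",
    n_segments(x), n_terminals(x), x$gamma, x$Q_in, x$r0))
  invisible(x)
}

#' Edge-table view of a tree
#'
#' @param x a `vascular_tree`.
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return a data.frame with one row per vessel.
#' @export
as.data.frame.vascular_tree <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(id = x$id, parent = x$parent,
             xp_x = x$xp[, 1], xp_y = x$xp[, 2], xp_z = x$xp[, 3],
             xd_x = x$xd[, 1], xd_y = x$xd[, 2], xd_z = x$xd[, 3],
             r = x$r, beta = x$beta, Q = x$Q, mu = x$mu,
             nterm = x$nterm, stage = x$stage,
             stringsAsFactors = FALSE)
}
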