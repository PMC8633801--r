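# Sequential constructive growth: stage configuration, candidate machinery,
# and the terminal-addition loop.

#' Stage configuration for constructive growth
#'
#' One growth stage adds `N` terminal vessels under a fixed parameter set.
#' Multi-stage protocols chain several configurations with [run_stages()],
#' typically relaxing the neighbourhood factor `f_n` as the tree refines.
#'
#' @param N terminals to add (>= 0).
#' @param gamma branching exponent.
#' @param delta daughter radius-symmetry constraint: candidate bifurcations
#'   with `min(r_l, r_r) / max(r_l, r_r) < delta` are rejected (0 disables).
#' @param f_r relaxation factor applied to the minimum-distance criterion
#'   after every 10 failed candidate points.
#' @param f_n neighbourhood size factor: the `max(1, round(f_n N_term^{1/3}))`
#'   closest vessels are considered as parents.
#' @param n_bif number of trial bifurcation points placed on a deterministic
#'   barycentric lattice strictly inside the triangle spanned by the parent
#'   endpoints and the candidate terminal position.
#' @param theta_min minimum angle (degrees) between the two daughter
#'   directions at a new bifurcation.
#' @param phi_min minimum deviation (degrees) of each daughter from the
#'   parent direction (0 disables).
#' @param k_d prefactor of the minimum-distance criterion
#'   `d_crit = k_d (V / (N + 1))^{1/3}`.
#' @param relax_floor growth aborts when the cumulative relaxation falls
#'   below this floor.
#' @param in_sample interior points per segment for the in-domain test.
#' @param in_check `"all"` (the three provisional segments must lie inside
#'   the domain) or `"new"` (only the new terminal segment; for setups whose
#'   initial network legitimately crosses the domain boundary).
#' @param cost a [cost_functional()].
#' @param viscosity a [viscosity_model()] used during this stage.
#' @param tag stage tag recorded on vessels created in this stage.
#' @param seed optional per-stage seed (otherwise the seed passed to
#'   [grow()] is used).
#' @param domain optional per-stage domain for [run_stages()].
#' @return an object of class `stage_config`.
#' @export
stage_config <- function(N, gamma = 3, delta = 0, f_r = 0.9, f_n = 1,
                         n_bif = 7L, theta_min = 0, phi_min = 0, k_d = 0.25,
                         relax_floor = 1e-3, in_sample = 5L,
                         in_check = c("all", "new"),
                         cost = cost_functional("volumetric", gamma = gamma),
                         viscosity = viscosity_model("constant"),
                         tag = "stage", seed = NULL, domain = NULL) {
  in_check <- match.arg(in_check)
  stopifnot(N >= 0, n_bif >= 1, f_r > 0, f_r <= 1, f_n > 0, k_d > 0)
  structure(list(N = as.integer(N), gamma = gamma, delta = delta, f_r = f_r,
                 f_n = f_n, n_bif = as.integer(n_bif), theta_min = theta_min,
                 phi_min = phi_min, k_d = k_d, relax_floor = relax_floor,
                 in_sample = as.integer(in_sample), in_check = in_check,
                 cost = cost, viscosity = viscosity, tag = tag, seed = seed,
                 domain = domain),
            class = "stage_config")
}

.stage_to_cpp <- function(stage) {
  list(gamma = stage$gamma, delta = stage$delta, f_r = stage$f_r,
       f_n = stage$f_n, n_bif = stage$n_bif, theta_min = stage$theta_min,
       phi_min = stage$phi_min, k_d = stage$k_d,
       relax_floor = stage$relax_floor, in_sample = stage$in_sample,
       in_check = stage$in_check,
       cost = list(kind = stage$cost$kind, c_v = stage$cost$c_v,
                   c_p = stage$cost$c_p, c_d = stage$cost$c_d,
                   V_ref = stage$cost$V_ref, l_ref = stage$cost$l_ref,
                   r_ref = stage$cost$r_ref),
       viscosity = unclass(stage$viscosity))
}

#' Neighbourhood of a candidate terminal position
#'
#' The `max(1, round(f_n N_term^{1/3}))` vessels closest to `x_new` by
#' point-to-segment distance, ordered by (distance, id).
#'
#' @param tree a `vascular_tree`.
#' @param x_new candidate position (cm).
#' @param f_n neighbourhood size factor.
#' @param restrict_allowed only consider vessels flagged as eligible parents
#'   (used during subdomain growth).
#' @return integer vector of vessel ids.
#' @export
neighbourhood <- function(tree, x_new, f_n = 1, restrict_allowed = TRUE) {
  cpp_neighbourhood(.tree_to_cpp(tree), as.numeric(x_new), f_n,
                    restrict_allowed)
}

#' Trial bifurcation points inside the connection triangle
#'
#' A deterministic barycentric lattice strictly inside the triangle spanned
#' by the parent endpoints and the candidate terminal position, ordered by
#' closeness to the centroid (`n_bif = 1` yields the centroid).  A degenerate
#' (collinear) triangle yields no candidates.
#'
#' @param x_pp,x_pd parent proximal and distal endpoints (cm).
#' @param x_new candidate terminal position (cm).
#' @param n_bif number of points.
#' @return matrix (`n_bif` x 3), possibly with zero rows.
#' @export
candidate_bifurcation_points <- function(x_pp, x_pd, x_new, n_bif = 7L) {
  cpp_candidate_points(as.numeric(x_pp), as.numeric(x_pd), as.numeric(x_new),
                       as.integer(n_bif))
}

#' Check one provisional connection
#'
#' Validity requires: the provisional segments lie inside the domain; the
#' daughter opening angle is at least `theta_min` and each daughter deviates
#' from the parent direction by at least `phi_min`; the daughter radii (after
#' a provisional rescaling pass) respect the symmetry bound `delta`; the new
#' terminal segment keeps a clearance of at least the sum of radii from all
#' non-adjacent vessels; and no segment is shorter than twice its radius.
#'
#' @param tree a `vascular_tree`.
#' @param parent_id vessel to split.
#' @param x_bif,x_new bifurcation and terminal positions (cm).
#' @param stage a [stage_config()].
#' @param domain a `perfusion_domain`.
#' @return list with `valid` (logical), `reason` (code string), and `dF`
#'   (cost increment when valid).
#' @export
is_valid_connection <- function(tree, parent_id, x_bif, x_new, stage, domain) {
  cpp_check_connection(.tree_to_cpp(tree), as.integer(parent_id),
                       as.numeric(x_bif), as.numeric(x_new),
                       .stage_to_cpp(stage), .domain_to_cpp(domain))
}

#' Best insertion of a candidate terminal position
#'
#' Enumerates all parents in the neighbourhood and all trial bifurcation
#' points, evaluates the cost increment `dF = F(T') - F(T)` on the fully
#' rescaled provisional tree (flows and radii updated), and returns the
#' strict minimum; ties break deterministically on (parent id, candidate
#' index).
#'
#' @param tree a `vascular_tree` (flows/radii are refreshed internally).
#' @param x_new candidate position, inside `domain`.
#' @param stage a [stage_config()].
#' @param domain a `perfusion_domain`.
#' @return list with `found`; when found also `parent_id`, `cand_index`,
#'   `x_bif`, `dF`, and `n_valid` (number of valid candidates examined).
#' @export
try_insert <- function(tree, x_new, stage, domain) {
  cpp_try_insert(.tree_to_cpp(tree), as.numeric(x_new),
                 .stage_to_cpp(stage), .domain_to_cpp(domain))
}

#' Grow a tree by sequential constructive optimization
#'
#' Adds `stage$N` terminal vessels: candidate positions are sampled uniformly
#' in `sample_domain`, must clear the minimum-distance criterion
#' `d_crit = k_d (V/(N+1))^{1/3}` (relaxed by `f_r` after every 10 failures),
#' and are connected at the valid bifurcation with the smallest cost
#' increment.  After the stage a viscosity/radius fixed point is run to
#' tolerance 1e-6.  The result is fully deterministic given
#' `(tree, seed, stream)`.
#'
#' @param tree initial `vascular_tree` (a single root segment or a loaded
#'   network).
#' @param domain `perfusion_domain` used for the in-domain constraint.
#' @param stage a [stage_config()].
#' @param seed integer seed (defaults to `stage$seed`, then to the domain
#'   seed).
#' @param stream sub-stream index for reproducible concurrent growth.
#' @param sample_domain domain candidates are drawn from (defaults to
#'   `domain`; a subdomain during partitioned growth).
#' @param keep_records log one insertion record
#'   `(x_new, x_bif, parent x_p, parent x_d)` per addition, returned as the
#'   `"records"` attribute (a data.frame).
#' @return the grown `vascular_tree`.
#' @export
grow <- function(tree, domain, stage, seed = NULL, stream = 0L,
                 sample_domain = domain, keep_records = FALSE) {
  if (is.null(seed)) seed <- if (!is.null(stage$seed)) stage$seed else domain$seed
  ct <- .tree_to_cpp(tree)
  levels <- attr(ct, "stage_levels")
  if (!stage$tag %in% levels) levels <- c(levels, stage$tag)
  ct$stage_code <- match(tree$stage, levels)
  res <- cpp_grow(ct, .domain_to_cpp(domain), .domain_to_cpp(sample_domain),
                  .stage_to_cpp(stage), stage$N, as.double(seed),
                  as.double(stream), match(stage$tag, levels), keep_records)
  out <- .tree_from_cpp(res$tree, levels)
  if (keep_records) {
    rec <- as.data.frame(res$records)
    names(rec) <- c("xn_x", "xn_y", "xn_z", "xb_x", "xb_y", "xb_z",
                    "pp_x", "pp_y", "pp_z", "pd_x", "pd_y", "pd_z")
    rec$seq <- seq_len(nrow(rec))
    attr(out, "records") <- rec
  }
  out
}

#' Run a multi-stage growth protocol
#'
#' Stages are applied in order, each receiving the previous stage's output;
#' vessels carry the tag of the stage that created them.  A stage may carry
#' its own `domain` and `seed`; otherwise the arguments given here apply.
#'
#' @param tree initial `vascular_tree`.
#' @param stages list of [stage_config()] objects.
#' @param domain default `perfusion_domain`.
#' @param seed base seed; stage `i` uses stream `i`.
#' @return the final `vascular_tree`.
#' @export
run_stages <- function(tree, stages, domain, seed = domain$seed) {
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    dom <- if (!is.null(st$domain)) st$domain else domain
    tree <- grow(tree, dom, st,
                 seed = if (!is.null(st$seed)) st$seed else seed,
                 stream = i - 1L)
  }
  tree
}

# Table-style stage splitting: quotient/remainder of the integer division,
# remainder assigned to the last part.
#' Split a total terminal count into per-part counts
#'
#' `total %/% parts` terminals per part, with the remainder added to the last
#' part, so the counts sum exactly to `total`.
#'
#' @param total total number of terminals to distribute.
#' @param parts number of parts.
#' @return integer vector of length `parts`.
#' @export
split_quotient_remainder <- function(total, parts) {
  q <- total %/% parts; r <- total %% parts
  counts <- rep.int(as.integer(q), parts)
  counts[parts] <- counts[parts] + as.integer(r)
  counts
}
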