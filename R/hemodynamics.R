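# Poiseuille network haemodynamics: viscosity law, segment resistances,
# pressure field, and the fixed-point coupling between diameter-dependent
# viscosity and radius rescaling.

#' Blood viscosity model
#'
#' Either a constant effective viscosity or the diameter-dependent in-vitro
#' law capturing the Fahraeus-Lindqvist effect: the relative apparent
#' viscosity of blood in narrow tubes (Pries-type parameterization at a given
#' discharge haematocrit) scaled by the plasma viscosity.
#'
#' @param kind `"constant"` or `"diameter"`.
#' @param mu_cP constant model value (cP).
#' @param mu_plasma_cP plasma viscosity (cP) for the diameter-dependent law.
#' @param hd discharge haematocrit (dimensionless) for the diameter-dependent
#'   law.
#' @return an object of class `viscosity_model`.
#' @export
#' @examples
#' viscosity(40, viscosity_model("diameter"))
viscosity_model <- function(kind = c("constant", "diameter"), mu_cP = 3.6,
                            mu_plasma_cP = 1.2, hd = 0.45) {
  kind <- match.arg(kind)
  stopifnot(mu_cP > 0, mu_plasma_cP > 0, hd > 0, hd < 1)
  structure(list(kind = kind, mu_const_cP = mu_cP,
                 mu_plasma_cP = mu_plasma_cP, hd = hd),
            class = "viscosity_model")
}

#' Effective viscosity at a given lumen diameter
#'
#' @param d_um lumen diameter in micrometres (> 0); vectorized.
#' @param model a [viscosity_model()].
#' @return viscosity in cP.
#' @export
viscosity <- function(d_um, model = viscosity_model()) {
  if (any(d_um <= 0)) stop("viscosity requires positive diameters")
  as.numeric(cpp_viscosity(as.numeric(d_um), unclass(model)))
}

#' Poiseuille resistance of a cylindrical segment
#'
#' `R = 8 mu l / (pi r^4)` evaluated in CGS units and reported in
#' mmHg s / cm^3 (1 dyn/cm^2 = 7.50062e-4 mmHg).
#'
#' @param l length (cm), `r` radius (cm), `mu` viscosity (poise); vectorized.
#' @param r,mu see `l`.
#' @return resistance in mmHg s / cm^3.
#' @export
segment_resistance <- function(l, r, mu) {
  if (any(l <= 0) || any(r <= 0) || any(mu <= 0))
    stop("segment_resistance requires positive length, radius and viscosity")
  8 * mu * l / (pi * r^4) * 7.50062e-4
}

#' Solve the network pressure field
#'
#' Pressures follow Poiseuille's law segment by segment from the inlet, where
#' the reference (zero) pressure is placed: `p_dist = p_prox - Q R`, children
#' inheriting their parent's distal pressure.  Reported pressures are
#' therefore drops relative to the inlet (non-positive for positive flows).
#'
#' @param tree a `vascular_tree` with flows, radii and viscosities assigned.
#' @return an object of class `flow_solution`: data.frame with columns `id`,
#'   `p_prox`, `p_dist` (mmHg relative to the inlet), `resistance`
#'   (mmHg s / cm^3), plus attributes `iterations` and `residuals` when
#'   produced by [fixed_point_viscosity_radii()].
#' @export
solve_pressures <- function(tree) {
  sol <- cpp_solve_pressures(.tree_to_cpp(tree))
  out <- data.frame(id = tree$id, p_prox = sol$p_prox, p_dist = sol$p_dist,
                    resistance = sol$resistance)
  class(out) <- c("flow_solution", "data.frame")
  out
}

#' Couple diameter-dependent viscosity and radius rescaling
#'
#' Fixed-point (linearization) iterations alternating (a) a viscosity update
#' from the current diameters with (b) a radius rescaling pass, until the
#' maximum relative radius change drops below `tol`.  With a constant
#' viscosity model the loop converges in exactly one iteration.  Divergence
#' (possible for unrealistically small vessels, below the capillary scale
#' where the viscosity law itself is questionable) raises an error carrying
#' the residual history.
#'
#' @param tree a `vascular_tree`.
#' @param model a [viscosity_model()].
#' @param tol maximum relative radius change at convergence.
#' @param max_iter iteration cap.
#' @return list with `tree` (converged) and `solution` (a [solve_pressures()]
#'   result with convergence attributes).
#' @export
fixed_point_viscosity_radii <- function(tree, model = viscosity_model(),
                                        tol = 1e-6, max_iter = 100L) {
  stopifnot(tol > 0, max_iter >= 1)
  ct <- .tree_to_cpp(tree)
  res <- cpp_fixed_point(ct, unclass(model), tol, as.integer(max_iter))
  if (res$iterations < 0) {
    cond <- structure(
      class = c("vasctree_nonconvergence", "error", "condition"),
      list(message = sprintf(
             "viscosity/radius fixed point did not converge in %d iterations (final residual %.3g)",
             max_iter, tail(res$residuals, 1)),
           call = sys.call(-1), residuals = res$residuals))
    stop(cond)
  }
  tree <- .tree_from_cpp(res$tree, attr(ct, "stage_levels"))
  sol <- solve_pressures(tree)
  attr(sol, "iterations") <- res$iterations
  attr(sol, "residuals") <- res$residuals
  list(tree = tree, solution = sol)
}

#' Root-to-terminal pressure drops
#'
#' @param tree a `vascular_tree`.
#' @param solution a [solve_pressures()] result for `tree`.
#' @return numeric vector: positive pressure drop (mmHg) from the inlet to
#'   each terminal's distal end, in terminal-id order.
#' @export
terminal_pressure_drops <- function(tree, solution = solve_pressures(tree)) {
  idx <- match(terminal_ids(tree), solution$id)
  -solution$p_dist[idx]
}
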