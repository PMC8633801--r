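# Cost functionals driving the constructive optimization.

#' Cost functional for tree construction
#'
#' The per-vessel cost is either the classical intravascular volume
#' `F(v) = pi l r^2` (`kind = "volumetric"`) or the sprouting form
#'
#' \deqn{F(v) = c_v \frac{\pi\, l\, r^{\gamma-1}}{V_{ref}^{\gamma/3}}
#'            + c_p \frac{r}{r_{ref}}
#'            + c_d \left(\frac{l}{l_{ref}}\right)^2}
#'
#' with non-negative coefficients summing to one; the volumetric, proteolytic
#' and diffusion terms weigh maintenance volume, sprouting effort, and
#' oxygen-diffusion distance.  With `gamma = 3`, `c_v = 1` and `V_ref = 1`
#' the sprouting form reduces to the volumetric one.
#'
#' @param kind `"volumetric"` or `"sprouting"`.
#' @param c_v,c_p,c_d non-negative coefficients with `c_v + c_p + c_d = 1`
#'   (checked to 1e-12; only used by the sprouting form).
#' @param V_ref,l_ref,r_ref characteristic volume (cm^3), length (cm) and
#'   radius (cm) of the perfusion setting.
#' @param gamma branching exponent used by the sprouting form.
#' @return an object of class `cost_functional`.
#' @export
#' @examples
#' F <- cost_functional("sprouting", c_v = 0.999, c_p = 0, c_d = 0.001,
#'                      V_ref = 100, r_ref = 1, l_ref = 1)
cost_functional <- function(kind = c("volumetric", "sprouting"),
                            c_v = 1, c_p = 0, c_d = 0,
                            V_ref = 1, l_ref = 1, r_ref = 1, gamma = 3) {
  kind <- match.arg(kind)
  stopifnot(c_v >= 0, c_p >= 0, c_d >= 0, V_ref > 0, l_ref > 0, r_ref > 0)
  if (kind == "sprouting" && abs(c_v + c_p + c_d - 1) > 1e-12)
    stop("cost coefficients must satisfy c_v + c_p + c_d = 1")
  structure(list(kind = kind, c_v = c_v, c_p = c_p, c_d = c_d,
                 V_ref = V_ref, l_ref = l_ref, r_ref = r_ref, gamma = gamma),
            class = "cost_functional")
}

#' Per-vessel cost
#'
#' @param l,r vessel length and radius (cm); vectorized.
#' @param F a [cost_functional()].
#' @return numeric cost (dimensionless by the reference scales).
#' @export
vessel_cost <- function(l, r, F = cost_functional()) {
  if (F$kind == "volumetric") return(pi * l * r^2)
  g <- F$gamma
  F$c_v * pi * l * r^(g - 1) / F$V_ref^(g / 3) +
    F$c_p * r / F$r_ref + F$c_d * (l / F$l_ref)^2
}

#' Total tree cost: the sum of per-vessel costs
#'
#' @param tree a `vascular_tree`.
#' @param F a [cost_functional()].
#' @return total cost.
#' @export
tree_cost <- function(tree, F = cost_functional()) {
  if (n_segments(tree) == 0) return(0)
  sum(vessel_cost(segment_lengths(tree), tree$r, F))
}
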