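---
title: "Constructive synthesis of vascular trees: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructive synthesis of vascular trees: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctree)
```

## The model

`vasctree` builds synthetic arterial trees inside a three-dimensional
perfusion domain $\Omega$ by constrained constructive optimization (CCO).
A network is a rooted strict-binary tree $T$ of rigid cylindrical segments
$v = (r, x^p, x^d)$ with radius $r > 0$ and proximal/distal coordinates in
cm.  Terminal segments deliver an outflow $q_\mathrm{out}$ to the tissue;
with $N$ terminals the tree has exactly $2N - 1$ segments.

Construction minimizes a total cost $F(T) = \sum_{v \in T} F(v)$ greedily,
one terminal at a time.  Two per-vessel functionals are available:

* **volumetric**: $F(v) = \pi\, \ell\, r^2$, the intravascular volume;
* **sprouting**:
  $F(v) = c_v\, \pi \ell r^{\gamma-1} / V_\mathrm{ref}^{\gamma/3}
        + c_p\, r / r_\mathrm{ref}
        + c_d\, (\ell / l_\mathrm{ref})^2$,
  with non-negative coefficients $c_v + c_p + c_d = 1$ weighing maintenance
  volume, sprouting (proteolytic) effort and diffusion distance.  For
  $\gamma = 3$, $c_v = 1$, $V_\mathrm{ref} = 1$ it reduces to the volumetric
  form.

Each accepted terminal is connected at the bifurcation position that
minimizes the cost increment $\delta F = F(T') - F(T)$, where the
provisional tree $T'$ is **fully** re-scaled (flows and radii) before
costing — the increment is a genuine difference of total costs, not a local
surrogate.

### Haemodynamics and radius scaling

Flows are prescribed through the terminals: under the uniform policy every
terminal carries $Q_\mathrm{in}/N$; during partitioned growth, terminals
outside the active subdomain keep their outflow frozen and the remainder is
split evenly inside.  Internal flows are exact bottom-up sums, so
conservation holds to machine precision.

Radii follow the branching power law $r_p^\gamma = r_l^\gamma + r_r^\gamma$
closed by the *equal-terminal-pressure* condition: at every bifurcation the
daughter radii satisfy $(r_l/r_r)^4 = (Q_l R^*_l)/(Q_r R^*_r)$, where
$R^*$ is the subtree's Poiseuille resistance reduced to unit subtree-root
radius through the recurrence
$R^*_i = \frac{8 \mu_i \ell_i}{\pi} + \left(\beta_l^4 / R^*_l +
\beta_r^4 / R^*_r\right)^{-1}$,
$\beta_l = (1+\xi^\gamma)^{-1/\gamma}$, $\beta_r = (1+\xi^{-\gamma})^{-1/\gamma}$,
$\xi = r_r / r_l$.  A leaf-to-root sweep computes $R^*$ and the $\beta$
factors; a root-to-leaf sweep propagates absolute radii from the fixed root
radius $r_0$ (an input, never derived from a pressure target).  The closure
makes all terminal pressures equal; the test suite verifies this against an
independent dense linear solve of the network.

Blood viscosity is either constant (default 3.6 cP) or diameter-dependent:
the in-vitro relative-viscosity law of the Fåhræus–Lindqvist effect at
discharge haematocrit $H_d$ (default 0.45), scaled by the plasma viscosity
(default 1.2 cP).  The source work cites the effect without printing the
formula or its parameters, so these canonical defaults are package choices
and both are configurable.  Because viscosity depends on diameter and
diameter on viscosity, the two are coupled by plain fixed-point iterations
(no damping; a relaxation hook was considered unnecessary since the
iteration converged in every tested configuration): update $\mu$ from the
current diameters, re-scale radii, repeat until the maximum relative radius
change falls below `tol` (default $10^{-6}$, cap 100 iterations).  With a
constant model the loop converges in exactly one iteration.  Hitting the
cap raises an error carrying the residual history.  At sub-capillary scales
the in-vitro law is bounded, so the iteration does not actually diverge
there in this implementation — the failure mode surfaces through the cap.

Pressures follow Poiseuille's law from the inlet, where the reference
(zero) pressure sits; reported values are therefore signed drops relative
to the inlet, in mmHg ($1\,\mathrm{dyn\,cm^{-2}} = 7.50062\times10^{-4}$
mmHg).  All internal computation is CGS.

### The growth loop

For each new terminal a candidate position is drawn uniformly in the
sampling region (rejection from the bounding box) and must clear the
occupancy criterion $d_\mathrm{crit} = k_d\, (V/(N+1))^{1/3}$ (point-to-
segment distance to the existing tree; $k_d$ default 0.25, $V$ and $N$
taken from the sampling region).  After every 10 failures the criterion is
relaxed by the factor $f_r$ (default 0.9, the staged value of the source
protocol); below the relaxation floor growth aborts with diagnostics.

Connections are searched over the $\max(1, \lfloor f_n N^{1/3}\rceil)$
nearest vessels and, per parent, over `n_bif` trial bifurcation points on a
deterministic barycentric lattice strictly inside the triangle spanned by
the parent endpoints and the candidate position (ordered by closeness to
the centroid, so `n_bif = 1` is the centroid; a collinear triangle yields
no candidates).  A connection is valid when (a) the provisional segments
lie inside the domain (sampled at 5 interior points each; configurable),
(b) the daughter opening angle is at least `theta_min` and daughter-parent
deviations at least `phi_min`, (c) the daughter radius symmetry
$\min(r_l,r_r)/\max(r_l,r_r) \ge \delta$, (d) every provisional segment
clears every vessel it does not meet at a junction by at least the sum of
radii, and (e) no segment is shorter than twice its radius.

Check (d) deliberately covers all **three** provisional segments, not only
the new terminal: splitting a parent bends its corridor into an elbow
(stub + sibling), and an unchecked elbow can invade a neighbouring vessel's
corridor.  With the extended check the post-hoc all-pairs clearance
property holds on every tree the suite builds.  Adjacency is "shares a
junction coordinate", which is sound because splits carry coordinates
through bitwise.

Ties in $\delta F$ break deterministically on (parent id, candidate index);
ids are never reused (a split retires the parent's id and issues fresh ids
for stub, sibling and terminal), which keeps merge bookkeeping unambiguous.
Growth is bit-reproducible given (tree, seed, stream): the engine uses its
own xoshiro256++ generator, so results are independent of R's RNG state,
and each subdomain draws from a stream derived from (seed, subdomain
index).

### Partitioned (parallel) construction

The scalable pipeline has three phases:

1. **Baseline**: grow a tree with $N_\mathrm{base}$ terminals over the whole
   domain sequentially; it carries the macro-scale structure.
2. **Subdomain growth**: partition the region into disjoint axis-aligned
   cells.  In cell $i$, only baseline vessels whose *midpoint* lies in the
   cell (plus vessels created there) may be split — the half-open cell
   labelling makes midpoint membership a function, so no vessel can
   bifurcate in two subdomains.  Candidate points are sampled inside the
   cell; collision checks remain global; outside terminals keep their
   frozen outflow.  Every insertion is logged as a record
   $(x_\mathrm{new}, x_\mathrm{bif}, x^p_\mathrm{parent}, x^d_\mathrm{parent})$.
   Because the phases share no mutable state, cells may be processed
   serially or concurrently with bit-identical results (asserted by test).
3. **Merge**: replay all record lists onto the baseline (ascending
   subdomain index, each list in order — the cross-list order is irrelevant
   by disjointness, also asserted by test), resolving each record's parent
   by its exact full-precision coordinate pair in a lookup table maintained
   under splits.  Radii are *not* rescaled during replay; after all
   insertions the terminal outflows are redistributed homogeneously and one
   global viscosity/radius fixed point restores the power law and the
   pressure closure.

The merged network has exactly $N_\mathrm{base} + \sum_i N_i$ terminals.
When only a total is given, per-subdomain counts default to the
quotient/remainder split of the integer division (remainder to the last
cell).

## Parameters that matter

| parameter | meaning | default | units |
|---|---|---|---|
| `gamma` | branching exponent | 3 | — |
| `r0` | root radius (fixed input) | per experiment | cm |
| `Q_in` | inlet flow | per experiment | cm³/s |
| `f_n` | neighbourhood factor on $N^{1/3}$ | 1 | — |
| `n_bif` | trial bifurcation points | 7 | — |
| `f_r` | distance-criterion relaxation | 0.9 | — |
| `k_d` | occupancy prefactor | 0.25 | — |
| `delta` | daughter symmetry bound | 0 (off) | — |
| `theta_min`, `phi_min` | angle constraints | 0, 0 | degrees |
| `tol` | fixed-point radius tolerance | 1e-6 | relative |

The staged protocol of the kidney-style setup maps onto lists of
`stage_config()` objects: the trial-point column of that protocol is read
as `n_bif` (its values shrink with refinement, consistent with a per-parent
trial count), `f_n` decreases stage by stage to localize the search, and
the always-1.0 leading entry of the optimizer tuple has no documented
meaning — it is accepted in configs and ignored.

## What the generator emulates — and what it does not

The synthetic domains are analytic boxes or watertight surface meshes; the
experiments ship with the cuboid geometries of the source protocol (the
4×1×1 comparison box, the side-2 multi-inlet cube, the 5×5×2.3 scalability
slab) at reduced terminal counts (hundreds to a few thousand instead of
5 000–100 000), chosen so the full suite runs on one CPU in minutes.  A
green suite therefore establishes algorithmic correctness (count laws,
conservation, closure, determinism, merge consistency) and *scaled-down*
agreement between sequential and partitioned construction; it does not
certify morphometric realism against measured vasculature, the organ-scale
geometry (which is not reproduced), or wall-clock scalability claims.

The multi-inlet seed is a synthetic stand-in: the reference external
network is not published, so a seven-segment tree with four
boundary-crossing branches is handcrafted, the outside vessels are excluded
from parent candidacy, and only the new terminal segment is required to lie
inside the domain (`in_check = "new"`) — under the strict all-segments rule
no connection to a boundary-crossing parent could ever be valid.

## Numerical choices, degenerate inputs

* Exact coordinate keys (full-precision doubles) identify parents during
  merge; any re-rounding would break resolution, so records serialize at 17
  significant digits and CSV/VTK writers do the same (round trips are
  bitwise).
* Box membership is closed; partition labelling is half-open per axis with
  the last cell closed, so every point has exactly one label.
* Mesh membership uses ray-crossing parity with a retry ladder of eight
  directions against edge-grazing rays; non-watertight surfaces are
  rejected at construction, and mesh volumes come from the divergence
  theorem (partition cells of mesh domains fall back to a seeded
  Monte-Carlo estimate that only feeds the occupancy heuristic).
* Degenerate candidate triangles (collinear) produce "no candidates", not
  errors; a zero-length segment anywhere is a hard error.
* The per-insertion viscosity treatment is the linearization: candidates
  are evaluated at frozen per-vessel viscosities, one sweep follows each
  acceptance, and the full fixed point runs at stage end.

## Known limitations

* Generation-wise medians of radius and pressure jitter between adjacent
  generations: CCO generations are heterogeneous (an often-split trunk
  piece carries a deep generation number), so only the per-generation
  maximum pressure is order-guaranteed, and the suite asserts the declining
  trend rather than strict median monotonicity.
* The greedy construction is not globally optimal, and the partitioned
  variant is by design a further relaxation; the suite quantifies the gap
  through the relative intravascular volume error at matched seeds rather
  than asserting optimality.
* Post-optimization of existing bifurcation positions, venous/capillary
  networks, vessel curvature and pulsatile flow are out of scope.

## A small worked pipeline

```{r example, eval = FALSE}
dom  <- box_domain(c(0, 0, 0), c(4, 1, 1))
part <- partition_axis_aligned(dom, c(4, 1, 1))
root <- vascular_tree(c(0, 0.5, 0.5), c(0.4, 0.5, 0.5),
                      r0 = 0.075, Q_in = 0.002)
res <- pdcco_pipeline(root, dom, part, N_base = 250, N_i = rep(63, 4),
                      stage = stage_config(N = 0,
                        viscosity = viscosity_model("diameter")),
                      seed = 1)
n_terminals(res$merged)        # 502 = 250 + 4 * 63
intravascular_volume(res$merged)
sol <- solve_pressures(res$merged)
head(generation_profile(res$merged, sol$p_dist))
```
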