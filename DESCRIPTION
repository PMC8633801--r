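Package: vasctree
Title: Constructive Synthesis of Vascular Trees with Domain-Decomposed
    Parallel Growth
Version: 0.1.0
Authors@R:
    person("vasctree", "developers", email = "vasctree@example.org",
           role = c("aut", "cre"))
Description: Generates optimized arterial trees inside three-dimensional
    perfusion domains by constrained constructive optimization (CCO) with
    staged, adaptive parameters, and scales the construction to large
    networks through a domain-decomposition strategy: a sequentially grown
    baseline tree is refined concurrently inside disjoint subdomains and
    the subnetworks are merged by record replay with deferred radius
    scaling.  Includes Poiseuille network haemodynamics with
    diameter-dependent (Fahraeus-Lindqvist) blood viscosity, Murray-type
    radius rescaling under a branching power law, Strahler-order and
    generation-wise morphometry, and CSV/VTK/JSONL interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
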