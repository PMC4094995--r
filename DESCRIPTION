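Package: fastgapfill
Title: Gap-Filling of Metabolic Reaction Networks by Linear Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Completes (gap-fills) a steady-state metabolic reaction network
    so that its flux-balance model achieves non-zero biomass flux. The core
    algorithm is an LP-only heuristic that binary-searches a weight delta on
    the biomass flux in the objective delta*f_b - sum(c_r*f_r) over a pool of
    candidate reactions, recording every growth-positive active candidate set;
    no integer variables are used, so each probe is a single linear program.
    Also provides a minimum-cost branch-and-bound gap-filler over binary
    inclusion variables as a ground-truth oracle for small instances, reaction
    preprocessing (reversible splitting, generic-reaction instantiation,
    growth-environment exchanges), a cost scheme keyed on reaction kind and
    taxonomic range, post-hoc verification and low-flux pruning of suggested
    reaction sets, and a deterministic synthetic-network generator for
    knockout benchmarks. Includes a bounded-variable revised simplex solver
    specialised to flux programs (S v = 0, 0 <= v <= u).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
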