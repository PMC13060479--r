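Package: poets
Title: Pareto Optimal Ensemble Techniques for Multiobjective Parameter Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates Pareto-optimal parameter ensembles for mechanistic models
    using multiobjective simulated annealing with strict Pareto dominance,
    incremental dominance-count ranking, and pop-on-reject archive management
    (Pareto Optimal Ensemble Techniques, POETs). Multiple independent annealing
    chains are merged and re-ranked to yield a dense cloud of near-optimal
    parameter sets from which prediction bands, parameter correlations,
    trajectory features, and coverage statistics are computed. Includes front
    quality indicators (hypervolume, inverted generational distance), the
    Binh-Korn and Fonseca-Fleming benchmark problems, and a two-state cell-free
    gene expression model with a synthetic time-course data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
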