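Package: psexplore
Title: Pattern Space Exploration of Simulation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open-ended, novelty-search-style evolutionary algorithm
    (Pattern Space Exploration) that drives the parameters of a stochastic
    simulator towards maximal diversity of output patterns, using a sparse
    hit-map archive over a discretised pattern space.  Ships a boids
    collective-motion model on a 2-D torus as the built-in test model,
    the three order parameters used to describe its collective phases
    (largest cluster size, relative diffusion, mean velocity), a-priori
    sampling baselines (regular grid, Latin hypercube, Sobol) and a
    benchmark harness comparing exploration methods by the number of
    distinct patterns discovered under equal evaluation budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    yaml,
    lhs,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deldir,
    igraph,
    optparse
Config/testthat/edition: 3
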