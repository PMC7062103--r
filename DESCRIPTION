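Package: culturedyn
Title: Population Dynamics of Cultural Paradigm Shifts on Epistatic Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of a well-mixed population distributed over
    the Boolean hypercube of cultural states. Fitness is given by seeded NK
    landscapes (optionally thresholded so that low-consistency states become
    incompatible) and drifts slowly between two endpoint landscapes through a
    convex combination. The population evolves by fitness-biased horizontal
    contagion with optional homophily and by guided variation, integrated with a
    fourth-order Runge-Kutta scheme in log-density variables. Quasi-static
    forward and backward parameter sweeps reproduce smooth versus abrupt
    (paradigm-shift) responses, hysteresis loops and initial-condition
    dependence, quantified with a Hamming-kernel similarity measure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    ggplot2,
    readr,
    rlang,
    generics,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
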