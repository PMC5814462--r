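Package: wtcascade
Title: Threshold-Driven Contagion on Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying monotone threshold-driven contagion on
    weighted networks. Provides a Monte Carlo simulator of the dynamical
    Watts threshold model with weighted influence and spontaneous adoption,
    approximate master equation (AME) solvers over degree/weight-type
    classes in both full and reduced form, combinatorial computation of
    phase boundaries in the (sigma, phi) parameter plane, cascade-speed
    observables, and generators for configuration-model networks with
    bimodal, lognormal or empirical weight distributions, including
    signed-network import.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    deSolve,
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
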