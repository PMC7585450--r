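Package: hypersis
Title: Mean-Field Theory and Stochastic Simulation of SIS Contagion on
    Hypergraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying susceptible-infected-susceptible (SIS)
    contagion on hypergraphs, where infection spreads both through pairwise
    links and through higher-order interactions (triangles and larger
    hyperedges). Implements the hyperdegree-based mean-field theory for
    collective contagion, individual contagion and higher-order healing, with
    degree-correlated or uncorrelated wiring of the higher-order structure;
    locates epidemic thresholds, fixed points and the onset of bistability
    (critical triangle infectivity, bistability index, phase diagrams) both
    numerically and from closed-form moment expressions; generates random
    hypergraphs with configuration-model-like wiring statistics; and provides
    an exact continuous-time stochastic simulator with the hysteresis sweep
    protocol used to detect explosive transitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
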