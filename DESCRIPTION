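Package: ffca
Title: Feasibility-Based Flux Coupling Analysis of Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flux coupling analysis (FCA) of stoichiometric metabolic networks
    at steady state. Implements FFCA, a feasibility-based algorithm that decides
    pairwise coupling relations (fully, partially, directionally coupled, or
    uncoupled) by testing small systems of linear equalities and inequalities
    over the steady-state flux cone, together with reversibility-type prunings
    and the Prev/Frev single-LP improvement. Also provides optimality-based
    flux-coupling-finder reference implementations (with and without reversible
    reaction splitting), an exact-arithmetic generator-enumeration oracle for
    verification on small networks, SBML and plain-text model input, a seeded
    synthetic-network generator, and tidy accessors for results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    xml2,
    withr,
    ggplot2,
    generics,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
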