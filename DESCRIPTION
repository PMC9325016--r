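Package: mofba
Title: Multi-Objective Flux Balance Analysis with NSGA-II
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constraint-based analysis of small metabolic networks with a
    multi-objective extension of flux balance analysis (FBA). Metabolic
    networks are read from plain-text reaction tables, FBA linear programs
    are solved with a bundled dense two-phase simplex, and trade-offs
    between several bioproduct fluxes are explored with a self-contained
    NSGA-II evolutionary algorithm whose genotype re-defines flux bounds
    for a chosen set of reactions. Includes the 18-reaction glycolysis
    module of Chlamydomonas reinhardtii as a built-in case study, an
    epsilon-constraint Pareto oracle, quality and diversity indicators,
    and a replicated experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    boot,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
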