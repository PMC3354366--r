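Package: gensem
Title: Bayesian Structural Equation Models and Causal Network Search for
    Pedigreed Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Searches for phenotypic causal networks among quantitative
    traits recorded on pedigreed populations. Fits recursive mixed-effects
    structural equation models (SEM) with additive genetic effects
    structured by the numerator relationship matrix via Gibbs sampling,
    applies the Inductive Causation (IC) algorithm to posterior samples of
    the residual covariance matrix conditional on genetic effects (highest
    posterior density interval decisions at multiple probability contents),
    orients edges with temporal prior knowledge, and compares competing
    structures with the deviance information criterion (DIC). Includes a
    synthetic-data generator producing pedigreed multi-trait datasets with
    known causal structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
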