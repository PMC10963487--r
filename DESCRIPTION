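Package: riskdag
Title: Ensemble Constraint-Based and Gradient-Based Causal Discovery for
    Survey Risk-Factor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Order-randomized ensemble causal structure learning for
    cross-sectional survey data with a designated binary outcome, built
    around non-suicidal self-injury (NSSI) risk-factor analysis in
    adolescents. Implements PC (original, stable, parallel) and FCI with
    Fisher-z conditional-independence tests, tiered background knowledge
    forbidding arrowheads into exogenous variables, edge-frequency
    consensus across many randomized variable orders, and an
    acyclicity-constrained graph autoencoder whose signed adjacency
    separates protective from risk factors. Ships a structural-causal-model
    survey simulator with ordinal discretization so every stage can be
    validated against known ground truth, plus preprocessing, descriptive
    rate tables, causal-neighborhood extraction and pathway enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    xml2
Config/testthat/edition: 3
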