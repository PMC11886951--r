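Package: statestack
Title: Stacked Prediction of Subject Traits from Models of Brain Network
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts individual subject traits from multivariate
    (e.g., parcellated fMRI) timeseries by fitting Gaussian hidden Markov
    models of network dynamics, extracting Riemannian tangent-space
    features from the state covariance matrices, running deconfounded
    kernel ridge regression, and combining many base-level predictions by
    stacked generalisation with simplex-constrained weights inside a
    nested, family-aware cross-validation scheme.  Includes a synthetic
    cohort generator with subject-specific state dynamics, family
    structure and confound effects, plus evaluation statistics
    (coefficient of determination, corrected repeated k-fold t-test,
    Benjamini-Hochberg FDR, Levene's test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
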