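Package: relapsim
Title: Simulation-Based Benchmark of Relapse Prediction from Leukemia Remission Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates synthetic cohorts of acute (AML) and chronic (CML)
    myeloid leukemia patients from mechanistic ordinary-differential-equation
    models of treatment response, degrades the simulated remission curves
    through a controlled data-quality ladder (measurement noise, clinical
    sampling sparsity, assay detection limit, refined measurement and dosing
    schemes), and benchmarks three relapse-prediction approaches --
    mechanistic model refitting, logistic regression on explicit time-course
    features, and a bidirectional LSTM sequence classifier -- under
    stratified 10-fold cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
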