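Package: trialERP
Title: Single-Trial ERP Amplitude Modeling with Regularized-Horseshoe
    Hierarchical Regression and Generalizability-Theory Reliability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking single-trial response-locked EEG component
    amplitudes (correct-response negativity and error-related negativity) to
    behavior and individual traits. Implements continuous-EEG cleaning
    (Butterworth filtering, neighbor interpolation, average reference, and a
    cross-channel spectral-correlation bad-segment detector), evoked-subtraction
    single-trial amplitude extraction at FCz, a hierarchical Bayesian
    regression with regularized horseshoe priors and a Student-t likelihood
    fit by a blocked Gibbs sampler, generalizability-theory internal
    consistency and fixed-effects dependability coefficients, a rank-constrained
    Bayesian multivariate regression for behavioral outcomes, and a synthetic
    go/no-go cohort generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    coda,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
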