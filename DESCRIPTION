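Package: sftrules
Title: Systems Factorial Technology and Logical-Rule Models for
    Composite-Face Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing the processing architecture underlying
    categorization of composite (two-part) stimuli such as schematic faces.
    Implements the nonparametric Systems Factorial Technology statistics
    (mean and survivor interaction contrasts, stochastic-dominance tests,
    deflection tests with permutation and asymptotic nulls, bootstrap
    confidence bands), parametric logical-rule models built from General
    Recognition Theory perceptual representations and Linear Ballistic
    Accumulator channel dynamics (serial, parallel, coactive, mixture and
    contaminant variants), simulation-based likelihoods via probability
    density approximation, differential-evolution MCMC posterior sampling
    with DIC model comparison, confirmatory individual-differences
    multidimensional scaling of similarity ratings, and equal-variance
    signal-detection analysis of the composite-face task. Includes seeded
    synthetic-data generators for every analysis so the full pipeline can
    be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
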