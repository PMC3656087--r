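Package: neurogpc
Title: Gaussian Process Classification of Structural Brain Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Probabilistic diagnostic classification of voxel-based
    morphometry data. Implements linear-kernel Gaussian process
    classifiers (expectation propagation for binary probit models,
    Laplace approximation for multiclass softmax models), leave-one-out
    cross-validation with matched pairs, permutation significance
    testing, probabilistic performance metrics (balanced accuracy, ROC
    AUC, target information), voxel-space discriminative weight maps,
    and a mass-univariate voxel-wise t-test with permutation-based
    cluster-level family-wise error correction. Includes a synthetic
    cohort generator that emulates smoothed modulated grey-matter volume
    maps with localized group effects and group-structured covariates,
    so the full pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
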