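Package: kernelmix
Title: Multiple Kernel Learning for Clinical and Omics Data Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Build binary classifiers that integrate heterogeneous data
    sources through multiple kernel learning (MKL). Provides Gram matrix
    construction for continuous and clinical (nominal, ordinal) features,
    a soft-margin support vector machine core with stratified
    cross-validation, three MKL solvers (closed-form Cauchy-Schwarz
    weight updates, reduced-gradient descent with line search, and a
    sparse dual augmented Lagrangian method with hinge or logistic loss),
    feature ranking and kernel screening against the no-information rate,
    gene-set kernels from GMT files, survival dichotomization, and
    synthetic generators for a two-group Gaussian benchmark and a
    multi-source omics study with survival outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
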