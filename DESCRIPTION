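Package: sobologit
Title: Scalar-on-Image Logistic Regression with L1 and Sobolev Penalties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits logistic regression models in which the covariate is an
    image and the regression coefficient is itself an image.  Estimation
    combines an L1 penalty, which selects informative pixels, with a
    discrete Sobolev (grid-graph Laplacian) penalty, which encourages
    spatial smoothness of the coefficient image.  Provides the sparse
    adjacent-pixel difference operator, a coordinate-descent solver with
    soft-thresholding, regularization-path tuning by validation set or
    M-fold cross-validation, synthetic-data generators for AR-correlated
    Gaussian and Haar-wavelet image designs, and a replicated
    simulation-study harness reporting prediction and estimation error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
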