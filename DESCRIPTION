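Package: nmfkit
Title: Regularized Non-Negative Matrix Factorization with Missing Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Non-negative matrix factorization (NMF) by sequential
    coordinate-wise descent and by generalized multiplicative updates, under
    mean-square-error and Kullback-Leibler losses, with a unified family of
    L2 (ridge), angle (pairwise column inner product) and L1 (sparsity)
    penalties on both factors.  Missing entries of the target matrix are
    handled natively by dropping their loss terms, which yields NMF-based
    missing-value imputation, holdout-imputation selection of the
    factorization rank, and mask-guided factorization for applications such
    as tumour-content deconvolution against known expression profiles.
    Core solvers are implemented in C++ via Rcpp and RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
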