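Package: stabnet
Title: Stability-Selected Partial-Correlation Networks for Trait-ERP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of sparse Gaussian graphical models by an adaptive
    random-penalty graphical lasso with bootstrap stability selection, and a
    stability toolbox for the resulting partial-correlation networks:
    node predictability (in-sample and hold-out), degree and current-flow
    centralities, maximal spanning trees, bootstrapped edge-weight confidence
    intervals, edge sensitivity/specificity, paired difference tests,
    train/test network similarity (Pearson and Hamming), and case-dropping
    measure-stability curves. Includes event-related potential (ERP)
    quantification (windowed mean amplitude, fractional-area latency,
    trial variability, subject-level dependability with exclusion rules),
    Box-Cox normalization with a non-normality screen, and a synthetic-data
    generator with known sparse precision structure and trial-level epochs
    so that every stage of the pipeline can be validated against ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
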