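Package: noradex
Title: Multi-Experiment RNA-seq Differential Expression and
    Rank-Aggregation Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying treatment-responsive genes across
    heterogeneous bulk RNA-seq experiments, built around a negative-binomial
    count model. Provides transcript-to-gene aggregation restricted to
    protein-coding biotypes, low-expression filtering, trimmed mean of
    M-values (TMM) normalization, Cox-Reid adjusted-profile-likelihood
    dispersion estimation with empirical-Bayes shrinkage, genewise exact
    tests for two-group designs, quasi-likelihood F-tests for factorial
    designs, a conditional false-discovery-rate rule for interaction terms,
    one-step surrogate-variable estimation for batch correction,
    combined-response analysis of merged experiments, cumulative p-value
    rank aggregation, and deterministic report tables (volcano, heatmap
    scale, radial fold-change). A negative-binomial simulator with exported
    ground truth generates multi-experiment factorial designs for
    validation. All user-facing functions take data frames and return
    tibbles so pipelines compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
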