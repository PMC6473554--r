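Package: mdmgroup
Title: Group Analysis of Dynamic Effective Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-subject structure learning for multiregression dynamic
    models (MDMs): conjugate dynamic-linear-model scoring of directed
    networks from multivariate time series, exact DAG search by dynamic
    programming, four group-network estimators (virtual typical subject,
    common structure, individual structure, and group structure via a
    pairwise log-Bayes-factor separation with clustering), and penalized
    multi-network estimators (IEMN/MEMN) that couple individual, subgroup
    and group networks through a structural-Hamming-distance prior.
    Includes a seeded generator of multi-subject networked time series and
    evaluation harnesses (sensitivity/specificity, SHD, network log Bayes
    factors, HPD intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
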