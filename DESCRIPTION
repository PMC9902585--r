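Package: coassoc
Title: Entropy-Based Screening of Receptors Co-Associated with EMT and
    Cell-Cycle Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico screen for signaling receptors whose expression is
    simultaneously associated with epithelial-mesenchymal transition (EMT)
    and cell-cycle (mitotic) activity in transcriptomic data. Provides
    rank-binned control-gene activity scores, plugin Shannon entropy and
    multivariate mutual information by inclusion-exclusion (pairwise and
    three-way co-information) with permutation significance, the
    co-association screen with receptor filtering and Spearman
    directionality ranking, a cross-dataset conserved-correlation procedure
    with hypergeometric over-representation analysis, and a calibrated
    negative-binomial simulator with planted monotone signal for validating
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
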