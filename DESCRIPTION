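Package: surftf
Title: Affinity Regression Linking Cell-Surface Proteins to Transcription
    Factor Activities in CITE-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a regularized bilinear (affinity) regression model that
    explains single-cell gene expression as the interaction between
    transcription-factor regulons and cell-surface protein (ADT) expression,
    so that D W P' approximates Y. From the learned interaction matrix W the
    package infers per-cell transcription-factor activities (W P') and
    projected surface-protein activities (Y' D W), assesses their
    significance against a permutation-based empirical null, benchmarks
    predictions against a nearest-neighbour baseline, and characterizes
    cell states via pathway co-occurrence enrichment and protein-based
    clustering with differential testing. Includes readers for
    CellRanger-style matrices and regulon edge lists, the normalizations
    appropriate for CITE-seq (log-normalization, centered log-ratio), and a
    fully seeded synthetic-data generator emulating the assumed data
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    generics,
    ggplot2,
    methods,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
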