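Package: dlingam
Title: DirectLiNGAM Causal Discovery for Health-Checkup Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates causal orderings and structural coefficient matrices
    among numeric health-checkup indices with the DirectLiNGAM algorithm for
    linear non-Gaussian acyclic models. Provides a synthetic checkup-data
    generator with a planted lower-triangular structural model and
    non-Gaussian disturbances, a cleaning pipeline (missing-record removal,
    per-index extreme trimming, standardization), entropy-approximation
    pairwise causal measures, root selection and deflation, elasticnet
    estimation of the structural matrix with Bonferroni edge pruning,
    bootstrap stability summaries, and causal-diagram export (DOT and CSV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
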