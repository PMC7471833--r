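Package: shapstab
Title: Shapley-Value Stability Selection for Multiscale Expression Data
Version: 0.1.0
Authors@R:
    person("Shapstab", "Maintainers", email = "maintainers@shapstab.dev",
           role = c("aut", "cre"))
Description: A pipeline for stratifying patients from multiscale genomic
    features (mRNA and microRNA expression blocks). Provides a synthetic
    expression-data generator with planted class-associated features, readers
    and per-block normalization for tab-delimited expression matrices, a
    Student's t-test feature filter, five classical feature rankers (fold
    change, OneR, ReliefF, information gain, gain ratio), exact and
    Monte-Carlo Shapley-value explainers with an efficient tree-path
    evaluator for the built-in randomized-tree ensemble, cross-fold
    Shapley-importance stability selection, and a classifier benchmark
    harness evaluated by accuracy, Matthews correlation coefficient and F1.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
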