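Package: mixscore
Title: Batch Effect Quantification Metrics and Simulation for Single-Cell Data
Version: 0.1.0
Authors@R:
    person("mixscore", "developers", email = "mixscore@posteo.net",
           role = c("aut", "cre"))
Description: Quantifies batch effects in single-cell RNA-seq data with a suite
    of cell-level, cell-type-level and global mixing metrics, centred on the
    cell-specific mixing score (a k-sample Anderson-Darling test on batch-wise
    k-nearest-neighbour distance distributions). Includes inverse Simpson
    (isi/wisi/lisi), neighbourhood entropy, the mixing metric, kBET-style
    chi-squared rejection rates, graph connectivity, batch silhouette and
    principal-component regression, together with a negative-binomial
    batch-effect simulator with tunable batch strength and a benchmark harness
    implementing label-permutation, batch-strength-scaling and batch-imbalance
    evaluation tasks with detection and imbalance limits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
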