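Package: scbfa
Title: Detection-Pattern Factor Analysis for Single-Cell Genomics
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Dimensionality reduction for single-cell RNA-seq and ATAC-seq
    data that models only the binary detection pattern (whether a feature
    received at least one read or UMI in a cell) with a penalized Bernoulli
    factor model, plus a fast Binary PCA approximation. Includes quality
    control and normalization utilities, highly-variable and highly-expressed
    gene selection, gene detection rate and dispersion diagnostics, a
    generative simulator with independent detection-noise and
    quantification-noise channels, and an evaluation suite (cross-validated
    Matthews correlation coefficient, averaged within-group sum of squares,
    marker-gene AUROC, clustering NMI/ARI, and plug-in batch correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
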