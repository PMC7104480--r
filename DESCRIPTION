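Package: epitensor
Title: Multi-Scale Deep Tensor Factorization for Epigenomic Track Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Imputes missing epigenomic signal tracks by modelling a
    (cell type x assay x genomic position) tensor with learned latent factors at
    three genomic resolutions (25 bp, 250 bp, 5 kbp) combined by a small
    feed-forward neural network trained with ADAM on mean squared error.
    Includes binned signal-track input/output (bedGraph, narrowPeak, BED,
    chrom.sizes), the two-stage pilot/per-chromosome training protocol with
    track-level cross-validation folds, an evaluation suite (six MSE variants,
    peak-count-stratified precision/recall/MSE, pairwise mark-relationship
    correlations, average precision), latent-feature extraction with
    cross-validated downstream prediction harnesses, integrated-gradients
    attribution of imputed values, and a seeded synthetic-compendium generator
    for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
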