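Package: mammatlas
Title: Cross-Dataset Mammary Cell Atlas Alignment and Hybrid Cell-State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns single-cell and bulk mammary transcriptomes onto a
    developmental reference atlas and analyses cell-state plasticity along the
    resulting trajectory. Provides quality control, global log-normalisation and
    stratified downsampling for UMI count matrices; mouse feeder-cell removal;
    randomized gene-subset ("CORGI"-style) selection of genes that induce shared
    low-dimensional structure across datasets; mutual-nearest-neighbour batch
    correction projecting queries onto a fixed reference; reference-anchored
    two-dimensional PCA with arrow-of-time pseudotime; marker-percentile
    classification of hybrid luminal/basal and epithelial/mesenchymal cell
    states; per-cell embryonic-stem-cell scores; and a negative-binomial
    branching-trajectory simulator with planted ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
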