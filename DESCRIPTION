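Package: sarcloc
Title: Segmentation of Sarcomeric Double-Line Structures in Single-Molecule
    Localization Microscopy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A machine-learning workflow for classifying localizations in
    single-molecule localization microscopy (SMLM) point clouds of sarcomeric
    proteins. Simulates labelled dSTORM-like localization data of double-line
    (disc pair) structures with clustered and uniform background noise, builds
    fixed-length per-localization feature vectors (350 sorted nearest-neighbour
    distances concatenated with a 30-bin orientation-aligned neighbour-direction
    histogram), trains a one-hidden-layer neural classifier, detects and expands
    regions of interest on rendered images, refines classifier-positive
    localizations with nearest-neighbour outlier, DBSCAN, and fit-quality
    filters, and estimates each object's line separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
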