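Package: momep
Title: Multi-Objective Multi-Expression Programming Classifiers for
    Grayscale Image Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves interpretable binary classifiers for grayscale medical
    images with multi-expression programming (a linear flavour of genetic
    programming in which every gene of a chromosome is the root of a
    candidate expression) under an NSGA-II style multi-objective search.
    Provides the image descriptors used as classifier inputs (statistical
    moments, histograms of oriented gradients, gradient kernel descriptors
    with kernel PCA compaction), four objective-combination models coupling
    a best-sub-expression selector with a maximised objective vector,
    Pareto-front majority voting over (classifier, threshold) pairs,
    data-complexity measures (Fisher discriminant ratio, class
    separability, points per dimension), a seeded synthetic-data generator
    for images and feature tables, and a non-parametric classifier
    comparison suite (wins/ties/losses, sign test, exact Wilcoxon
    signed-ranks, Friedman, Iman-Davenport, Nemenyi critical-difference
    diagrams).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
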