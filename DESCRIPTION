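Package: treehaar
Title: Haar-Like Wavelets, Covariance Sparsification and Beta-Diversity on
    Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds the Haar-like wavelet basis of a rooted (planted) binary
    phylogeny and uses it to pseudo-diagonalize the tree's ultrametric
    covariance matrix without ever materializing it densely. Simulates
    critical beta-splitting and uniform (Catalan) random binary trees,
    computes exact recursions and asymptotic expansions for the first and
    second moments of the external path length under the critical
    beta-splitting model, and provides the Haar-like beta-diversity distance
    between OTU abundance samples together with a multivariate
    hypergeometric permutation test for the statistical significance of its
    per-split components. Includes a synthetic paired-sample generator for
    calibration and power studies, tidy (tibble) outputs, broom-style
    tidiers, and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
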