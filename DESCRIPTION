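Package: noduleseg
Title: Deep-Network Segmentation, Counting and Sizing of Legume Root Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying root nodules of legumes
    (e.g. soybean) from RGB photographs of excavated root systems: a small,
    configurable U-Net style encoder-decoder trained on image/mask pairs,
    dense conditional-random-field refinement of the per-pixel probabilities,
    morphological closing and size-based noise removal, connected-component
    counting and mm^2 sizing against a physical reference scale, a
    semi-automatic annotation data layer (mask to polygon contours and back)
    supporting an error-correction and transfer-learning loop with pixel
    F1 evaluation, and the downstream randomized-complete-block-with-
    subsampling ANOVA, Tukey mean comparisons and per-treatment trait
    correlations. Includes a synthetic scene and phenotype generator with
    known ground truth so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: zlib
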