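Package: segcall
Title: Nanopore Basecalling by Instance Segmentation of Raw Current Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Basecalls nanopore current signals (squiggles) by per-sample
    instance segmentation. A one-dimensional U-net enhanced with recurrent
    layers assigns one of eight alias nucleotide labels to every current
    sample; collapsing runs of identical labels yields both the basecall and
    its per-base signal segmentation, with alias phases disambiguating
    adjacent identical bases in homopolymers. Includes the dice plus
    categorical cross-entropy training objective, soft merging of overlapping
    sliding-window predictions into whole-read calls, median/MAD signal
    normalization, a synthetic squiggle simulator with gold per-sample labels
    for fully self-contained training and evaluation, and alignment-based
    accuracy metrics (normalized edit distance, read accuracy and identity,
    assembly identity and relative length summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
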