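Package: traplife
Title: Trap-Based Time-Lapse Analysis of Yeast Replicative Lifespan
Version: 0.1.0
Authors@R:
    person("traplife", "developers", email = "traplife@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of mother-cell trap time-lapse microscopy:
    trap detection in fields of view by normalized cross-correlation,
    per-frame cell-state classification with a small convolutional network,
    sequence classification with a bidirectional LSTM, division counting and
    replicative-lifespan reconstruction from class oscillations, senescence
    entry point detection, semantic segmentation of mother cells and nuclei
    with fluorescence quantification, Kaplan-Meier/Greenwood survival and
    discrete hazard statistics, event-pairing benchmarks, and a synthetic
    trap-movie generator so the whole pipeline is trainable and testable at
    desk scale on a single CPU.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
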