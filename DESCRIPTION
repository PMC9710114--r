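Package: phasetcn
Title: Surgical Phase Recognition with Multi-Stage Temporal Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale toolkit for frame-level surgical workflow phase
    recognition in microscope video. Implements a residual multi-stage
    temporal convolutional network with causal dilated convolutions and
    dual dilated layers (opposing exponential dilation schedules capturing
    local and global temporal context), a triple-stream per-frame feature
    frontend that fuses whole-frame, pupil-patch and instrument-patch
    encodings, median-frequency-balanced weighted cross-entropy training
    objectives with a poly learning-rate schedule, frame-level macro
    evaluation metrics (accuracy, precision, recall, Jaccard), segment and
    transition-deviation analysis, phase-ribbon visualization, and a
    seeded synthetic surgery-video generator so every component is
    trainable and testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    caret,
    withr
Config/testthat/edition: 3
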