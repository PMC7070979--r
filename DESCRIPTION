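Package: emgartifact
Title: Motion-Artifact Suppression for Insulated Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Streaming time-domain feature extraction and shallow-classifier
    pipelines that distinguish true muscle contractions from motion artifacts
    in single-channel surface EMG, so that a myoelectric prosthesis drive is
    activated only during genuine contractions. Implements a bank of 26
    fixed-point feature state machines (zero- and mean-crossing rates,
    slope-sign change, waveform length, mean absolute value, Willison
    amplitude, variance), the digital pre-processing chain (averaging
    decimation, 50 Hz comb, low/high-pass stages, rectified envelope), a
    seeded synthetic EMG/artifact generator, dataset assembly with
    correlation pruning and min-max normalization, logistic-regression,
    CART, shallow neural-network and delay-1 recurrent-network training with
    transition-tolerant scoring, model quantization to a 1024 fixed-point
    scale, and online decision debouncing with envelope gating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    glmnet,
    rpart,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
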