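Package: eegdecode
Title: Single-Trial EEG Decoding with Compact Convolutional Networks and
    Gradient-Based Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, decoding and interpretation of epoched
    multi-channel EEG. Provides a synthetic evoked-potential generator with
    1/f background noise and planted class-conditional spatiotemporal
    components, a deterministic epoch-conditioning pipeline (zero-phase
    band-pass filtering, baseline correction, amplitude-based artifact
    rejection, subject-level normalization, class balancing), a compact
    convolutional classifier of the EEGNet family (temporal, depthwise-spatial
    and separable convolutions) trained with class-weighted cross-entropy and
    early stopping, Grad-CAM channel-by-time attribution maps, binomial-null
    bootstrap chance-level inference, and orchestration of cross-task
    generalization experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
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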