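Package: adlsound
Title: Activity-of-Daily-Living Recognition from Ambient Sound at the Edge
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An edge-style pipeline for recognizing Activities of Daily Living
    (ADL) from ambient household sound. Provides energy-gated capture of 16 kHz
    audio, streaming windowless 48-band log-Mel feature extraction with 8-bit
    affine quantization, balanced and mask-augmented training-set construction,
    a small residual convolutional network with emulated int8 inference,
    voting/tolerance post-processing that abstracts noisy per-frame predictions
    into activity logs, and a hub layer that merges and scores per-location
    logs. A parametric sound synthesizer generates every supported sound class
    and scripted multi-event sessions with ground truth for development and
    evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
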