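Package: protoerp
Title: Zero-Calibration Prototype-Matching Decoding of Single-Trial RSVP ERPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Episodically meta-trained prototype network for single-trial
    target detection in rapid serial visual presentation (RSVP) EEG, decoding a
    held-out subject with no calibration data. A multiscale convolutional
    encoder with squeeze-and-excitation and efficient-channel-attention blocks
    maps an epoch to a 1024-dimensional feature vector; class prototypes are
    subject-attention-weighted means of support-subject class features, and the
    prototype distance is feature-attention-weighted. Includes a synthetic
    multi-subject ERP cohort simulator (rare targets, subject-specific
    amplitude/latency/topography, AR(1) background noise), 2-30 Hz zero-phase
    Butterworth preprocessing, leave-one-subject-out evaluation with balanced
    accuracy, AUC and paired Wilcoxon tests, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
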