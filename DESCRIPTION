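Package: CogStateCNN
Title: Decoding Cognitive States from EEG Scalograms with an Attention CNN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for four-class cognitive-state decoding (resting, mental
    memory recall, mental singing, serial subtraction) from multi-channel
    EEG. Raw 59-channel recordings are band-pass filtered, average
    referenced, baseline corrected and cut into non-overlapping windows;
    each window is converted with a complex Morlet continuous wavelet
    transform into a 177-plane band-split scalogram stack (59 electrodes x
    3 frequency bands, each plane 60 x 100), which a convolutional network
    with a channel-and-frequency attention block classifies. Includes a
    seeded synthetic EEG generator emulating the block-design acquisition
    protocol, EDF+ input/output, a five-fold cross-validation trainer with
    Adam optimisation written in C++, a multiclass metric suite (accuracy,
    macro precision/recall/F-score, Cohen's kappa, macro one-vs-rest AUC),
    window-length sweeps, and scalp topography export of the learned
    attention weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    pROC,
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
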