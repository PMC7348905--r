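Package: timingbci
Title: Single-Trial Decoding of Sub-Second Timing Prediction from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding covert timing prediction (e.g. anticipating an
    event 400 ms versus 600 ms after a cue) from single-trial epoched EEG.
    Implements the full analysis pipeline: a labelled epoch container with a
    portable on-disk bundle format, zero-phase Butterworth band decomposition
    and baseline correction, descriptive ERP metrics (window amplitude,
    fractional-area latency, SNR, Fisher discriminative ratio, Morlet-wavelet
    ERSP), discriminative canonical pattern matching (DCPM) for low-frequency
    ERP features, common spatial patterns (CSP) for high-frequency power
    features, Fisher-discriminant decision-level fusion of the two
    classifiers, stratified k-fold cross-validation, a band-sweep and
    three-method comparison harness, and a synthetic EEG generator that
    emulates the contingent negative variation, post-expectancy positive
    deflection and beta/gamma power suppression so the whole pipeline is
    testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
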