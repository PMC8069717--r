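Package: eegfatigue
Title: EEG Channel Selection and Sparse Multi-Feature Fusion for Mental
    Fatigue Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects mental fatigue from multichannel EEG recordings.
    Implements ReliefF-based channel weighting with two common-channel
    aggregation schemes (normalized weight addition and single-channel
    accuracy weighting), five per-channel time/frequency features
    (sub-band Welch power spectral density in the delta, theta, alpha and
    beta bands, and sample entropy), sparse multi-feature fusion via K-SVD
    dictionary learning with orthogonal matching pursuit coding, and a
    spectral regression discriminant analysis (SRDA) classifier, together
    with a seeded synthetic EEG cohort generator with known informative
    channels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
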