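Package: ecgfb
Title: Frame-Blocking Preprocessing and Residual Attention Networks for
    Multi-Label 12-Lead ECG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for multi-label cardiac arrhythmia detection from
    12-lead electrocardiograms. Implements frame-blocking length
    unification (a fixed number of fixed-length, possibly overlapping
    frames per record), Butterworth lowpass denoising, per-class binary
    relevance with random under-sampling, a per-frame one-dimensional
    residual convolutional network feeding an attention-based
    bidirectional LSTM, the full precision/recall/F1/ROC/AUC evaluation
    suite with a paired Wilcoxon signed-rank comparison of preprocessing
    strategies, and a synthetic multi-lead ECG generator so the whole
    pipeline is exercisable without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
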