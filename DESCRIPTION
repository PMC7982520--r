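Package: erpdecode
Title: Single-Trial ERP Decoding with t-SNE Features and Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decodes binary decisions from single-trial event-related
    potential (ERP) epochs. Implements the full chain from epoched EEG to
    a classified decision: artifact handling (EOG regression, baseline
    correction, zero-phase low-pass filtering, peak-to-peak rejection,
    sweep-count gating), a from-scratch t-SNE feature extractor with
    perplexity-calibrated Gaussian affinities and momentum gradient
    descent, a from-scratch LSTM sequence-to-label classifier trained by
    stochastic gradient descent with momentum, six comparison
    architectures (recurrent PCA/ICA networks, a deep LSTM, SVM and
    back-propagation classifiers on t-SNE features, and a convolutional
    network on wavelet scalograms), a repeated-holdout evaluation harness
    with channel-subset montages, a scalp feature map, and a synthetic
    two-condition ERP generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
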