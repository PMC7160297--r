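Package: erspnet
Title: Deep-Learning Discrimination of Adult ADHD from Event-Related EEG
    Spectrograms
Version: 0.1.0
Authors@R: person("ERSP", "Maintainers", email = "maintainers@erspnet.org",
    role = c("aut", "cre"))
Description: A reusable, fully synthetic-testable pipeline for discriminating
    adult ADHD patients from healthy controls using event-related spectral
    EEG. Provides a flanker-task EEG cohort simulator (1/f background, tonic
    alpha, event-locked theta burst and N100 component), zero-phase band-pass
    filtering and baseline correction, single-trial Morlet-wavelet
    time-frequency stacks (22 log-spaced frequencies x 20 time bins x 7
    channels), three from-scratch neural-network classifiers (a four-layer
    convolutional network with exactly 75106 trainable parameters, a
    three-layer stacked LSTM, and a 1024-unit shallow network) trained with
    Adam under leave-pair-out cross-validation with inverse-probability age
    weighting, Wilcoxon-Mann-Whitney AUC, single-channel ablation, and
    activation-maximization (DeepDream) visualization of the learned
    class differences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
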