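Package: tffc
Title: Time-Frequency Fusion Contrastive Learning for Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Self-supervised representation learning for windowed multichannel
    time series (EEG sleep staging, seizure detection, activity and gesture
    recognition) via time-frequency fusion contrasting. Augmented views are
    built from a time-domain bank (jitter, scaling, permutation, masking) and
    a frequency-domain bank (low-pass, phase shift, remove/add frequency)
    fused through kernel PCA; a 1D residual encoder is pre-trained with the
    NT-Xent contrastive objective and evaluated after supervised fine-tuning.
    Includes a synthetic-signal generator with class-specific spectral and
    temporal structure so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    kernlab,
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
Config/testthat/edition: 3
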