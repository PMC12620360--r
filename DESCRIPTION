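Package: earstress
Title: Bilateral Ear-EEG Stress Detection with Bidirectional Cross-Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation, preprocessing, spectral-marker statistics, and a
    subject-independent deep classifier for two-channel bilateral ear-EEG
    stress detection under a rest-versus-rest paradigm. Provides a synthetic
    paired-condition EEG generator with controlled spectral effects, the
    Butterworth band-pass / notch / down-sampling preprocessing chain, seven
    canonical scalp-EEG stress markers with paired Wilcoxon signed-rank tests
    and Benjamini-Hochberg FDR control, a from-scratch convolutional encoder
    with pointwise temporal compression and bidirectional cross-attention
    between the two ear channels (plus ablation variants), eight-fold
    subject-level cross-validation with AdamW training and early stopping,
    and explainability analyses (attention entropy, directional asymmetry,
    zero-baseline temporal occlusion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    jsonlite,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
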