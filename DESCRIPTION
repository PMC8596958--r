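Package: deeptrait
Title: Deep Recurrent Ensembles for Trait Prediction from Resting-State fMRI Timeseries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a latent behavioral trait (a general-intelligence factor
    "g") from parcellated resting-state fMRI timeseries with an ensemble of
    two-layer additive bidirectional LSTM regressors, and interprets the
    trained models. Provides spectral band-pass filtering with decimation by
    spectral truncation, leakage-free confound decorrelation, family-stratified
    k-fold cross-validation, an elastic-net functional-connectivity baseline,
    region-set ablation with size-matched resampling nulls and FDR control,
    input-gradient saliency propagated through per-region standardization,
    saliency-defined networks, first-order propagation of saliency to
    functional connectivity, and propagation to ZCA-whitened innovations via
    SVD differentials. A synthetic-cohort generator with planted, recoverable
    trait effects makes every stage testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
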