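# deeptrait

Deep recurrent ensembles for predicting a latent behavioral trait from
parcellated resting-state fMRI timeseries — and for understanding what the
trained models rely on.

## The problem

A general-intelligence factor *g* (a latent scalar from factor analysis of
cognitive test batteries) is weakly predictable from resting-state brain
activity. The standard approach regresses *g* on resting-state functional
connectivity (RSFC) — the R×R matrix of Pearson correlations between regional
BOLD timeseries. `deeptrait` instead regresses *g* directly on the
timeseries with an ensemble of two-layer **additive bidirectional LSTMs**:
per session, the forward- and backward-direction LSTM outputs are summed at
each timestep, mean-pooled over time, and read out by an affine head; the
subject-level prediction is the flat mean over ensemble members and sessions.
With 360 regions and 256 hidden units the network has exactly 2,316,545
learnable parameters (632,320 per direction in layer 1, 525,824 in layer 2,
257 in the head) — counts the package's accounting reproduces and tests pin.

Around the regressor, the package implements the full analysis pipeline:

- **Preprocessing** — band-pass filtering to [0.008, 0.09] Hz with
  decimation by spectral truncation (a 1,200-point, 864-s session becomes
  exactly 155 points, virtual TR 5.57 s), per-region standardization, and
  leakage-free confound decorrelation of the trait (`R^2` of *g* on
  confounds ≈ 0.138 by default in the generator).
- **Family-stratified k-fold CV** — families never straddle folds; strata
  are terciles of family-averaged *g* × family size (1/2/3+).
- **Elastic-net RSFC baseline** — α = 0.05, 50-value λ path, inner 3-fold
  CV, univariate feature filter; the classical comparison model.
- **Ablation** — zero-fill region sets on validation data, paired-T
  degradation across folds, size-matched random-network resampling nulls
  (default 300 iterations), empirical p-values, Benjamini–Yekutieli or
  Benjamini–Hochberg FDR.
- **Saliency** — exact input gradients with standardization inside the
  differentiable graph (per region they sum to zero over time and are
  orthogonal to the data — enforced to 1e-8), temporal-variance summaries,
  cross-validated saliency-defined networks, first-order propagation to
  connectivity (δC = (DᵀX + XᵀD)/(T−1)) with IMPC/DMPC/DMNC/IMNC
  categorization of the top-5% effects, and propagation to ZCA-whitened
  innovations (Z = UVᵀ from the SVD of X) via analytic SVD differentials.
- **Synthetic cohorts** — Gaussian AR(1) sessions whose innovation
  covariance is modulated by the subject's trait in a planted salient-region
  block, plus family structure and trait-correlated confounds, so the whole
  pipeline is testable without access-restricted imaging data.

The BiLSTM forward/backward pass (backpropagation through time) is written
in RcppArmadillo; all gradient routes are verified against central finite
differences in the test suite.

## Worked example

```r
library(deeptrait)

cfg <- cohort_config(n_subjects = 150, n_regions = 20, n_timepoints = 240,
                     n_sessions = 2, seed = 7)
cohort <- preprocess_cohort(generate_dataset(cfg))
folds  <- make_folds(cohort$subjects, k = 4, seed = 7)
tc <- training_config(epochs = 30, learning_rate = 3e-3, weight_decay = 0.2,
                      max_crop = 5, batch_size = 16, ensemble_size = 3,
                      init_gain = 2, forget_bias = 1, seed = 7)
cv <- run_cv(cohort, folds, arch_spec(input_dim = 20, hidden_dim = 8), tc)
print(cv)

sa <- saliency_ablation_study(cv, cohort,
                              size = length(cohort$truth$salient_regions),
                              n_random = 10, seed = 7)
cat(sprintf("saliency-network mean delta R^2: %.3f vs random median: %.3f\n",
            sa$mean_delta_saliency, median(sa$mean_delta_random)))
```

Output:

```
<cv_run> k = 4 folds, 3 members/fold
  R^2   = 0.161 (stderr 0.031)
  rho^2 = 0.190 (stderr 0.036)
  MSE   = 0.855 (stderr 0.124)
saliency-network mean delta R^2: 0.417 vs random median: 0.075
```

The ensemble recovers part of the planted trait signal (cross-validated
R² = 0.161, squared correlation 0.190 at this deliberately small scale;
above 0.3 at the default testing scale of 300 subjects × 60 regions, as the
acceptance suite verifies), and
ablating the network of highest-saliency regions — defined on training
folds, ablated on validation folds — costs far more R² (0.417) than a
typical size-matched random region set (0.075), which is the package's
cross-validated evidence that saliency finds the regions the model actually
uses.

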