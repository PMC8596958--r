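---
title: "Predicting a latent trait from resting-state timeseries with recurrent ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting a latent trait from resting-state timeseries with recurrent ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A general-intelligence factor "g" — a latent scalar summarizing performance
across cognitive test batteries — is weakly but reliably predictable from
resting-state fMRI. The standard approach regresses g on resting-state
functional connectivity (RSFC), the matrix of Pearson correlations between
parcellated regional timeseries. `deeptrait` implements an alternative that
regresses g directly on the timeseries with an ensemble of bidirectional
recurrent networks, together with the machinery needed to understand *what*
such a model uses: ablation with size-matched resampling nulls, input-gradient
saliency, saliency-defined networks, first-order propagation of saliency to
connectivity, and propagation to ZCA-whitened innovations.

Because the motivating datasets (e.g. the Human Connectome Project) are
access-restricted, the package ships a synthetic-cohort generator that plants
the statistical structure the analysis assumes, so every downstream stage is
testable end to end without any download.

## Preprocessing

Regional timeseries are band-pass filtered to the slow BOLD band
[0.008, 0.09] Hz by hard spectral masking, and decimated by truncating the
spectrum at the upper cutoff: bins with frequency $k/\mathrm{duration}$
outside the band are zeroed (DC always), bins above
$k_{\max} = \lfloor f_{high} \cdot \mathrm{duration}\rfloor$ are discarded,
and the remainder is inverse-transformed onto $T' = 2k_{\max}+1$ samples.
Decimation this way is information-free for in-band signal and removes the
long-range autocorrelation a band-pass filter otherwise induces. A
1,200-point session spanning 864 s becomes exactly 155 points with a virtual
sampling interval of 864/155 = 5.57 s. We chose hard masking over an FIR/IIR
design because truncating the spectrum *is* the decimation rule; an
equivalent filter design would blur the bin-exact count $T'$. Band edges are
inclusive, at bin resolution; the Nyquist precondition is checked in bin
space so that re-filtering an already decimated series is exactly a no-op.

Each region is then standardized per session (mean 0, SD 1, divisor
$T-1$). The divisor matters: it is the same normalizer used for the saliency
temporal variance and for the $\delta C$ propagation below, so a
standardized column has squared norm exactly $T-1$ and the algebraic
invariants of the saliency (below) hold exactly.

The trait is decorrelated from confounds by OLS on *training* subjects only;
validation traits are residualized with the training coefficients and scaled
with the training residual mean/SD. This "fit on train, apply frozen"
discipline is asserted by tests.

## The regression model

Two bidirectional LSTM layers whose forward and backward per-timestep
outputs are *added*, followed by temporal mean pooling and an affine head.
One direction-LSTM with input $d$ and state $h$ has $4h(d+h)$ weights, $4h$
gate biases and $2h$ learnable initial states; with $d=360$, $h=256$ this
gives 632,320 parameters per direction in layer 1, 525,824 in layer 2, 257
in the head and 2,316,545 in total. Learnable initial states and a single
gate-bias vector are the only conventions that reproduce these counts, and
the accounting is pinned by tests.

Training minimizes per-session MSE against the subject's adjusted trait with
ADAM plus decoupled weight decay (applied to weight matrices only, by
default). Each batch independently crops up to `max_crop` timesteps at both
sequence ends; sessions are treated as independent samples and reshuffled
every epoch. Training is bit-reproducible given the config seed: every
random draw (init, shuffles, crops, member seeds, fold seeds) flows from a
master seed through named substreams.

Defaults mirror the reference setting (50 epochs, learning rate 5e-4, decay
5e-4, crop 20). Two initialization knobs are exposed because initialization
is otherwise unspecified: a Glorot gain multiplier and a constant forget-gate
bias. At desk scale we found `init_gain = 2`, `forget_bias = 1` necessary
for the network to pick up covariance structure rather than memorize; the
intuition is that larger input weights strengthen the gate-times-candidate
product terms through which an LSTM expresses instantaneous cross-region
products, and a positive forget bias lengthens the integration window over
which those products are averaged.

The ensemble prediction is the flat mean over members and sessions of the
per-session scalar outputs. `ensemble_size_curve()` recomputes validation
performance for every prefix of the ensemble in training order.

## Cross-validation

Folds are assigned to *families*, never subjects: families are stratified
into terciles of family-averaged g crossed with size groups (1, 2, 3+), and
dealt round-robin into k folds. Two choices were genuinely open. Ties at
tercile edges go to the lower tercile (deterministic and order-free). And
the recombination of per-stratum deals is under-specified in the source
description; we carry the dealing position across strata (balancing fold
sizes globally) and, within a stratum, seed-shuffle families and then stably
order them by family-averaged g before dealing. The pure shuffled deal left
per-fold trait means wandering beyond the 0.2-SD homogeneity bound the
test suite asserts at n = 900; the g-ordered deal keeps them comfortably
inside it while ties remain randomized.

Metrics: MSE; $R^2 = 1 - \mathrm{MSE}/\mathrm{Var}(y)$ with the population
variance (divisor n, so predicting the mean gives exactly 0); and the
squared Pearson correlation $\rho^2$. Fold summary is the mean and
$\mathrm{SD}/\sqrt{k}$ across folds.

The comparison model is an elastic net on session-averaged upper-triangle
RSFC features with mixing $\alpha = 0.05$ (near-ridge), a 50-value lambda
grid log-spaced four decades down from $\lambda_{\max}$, lambda selected by
inner 3-fold CV on training data only, and a univariate correlation-test
filter ($p < 0.01$ two-sided by default — the reference leaves the filter
statistic unstated, so it is exposed as configuration).

## Ablation and the size-matched null

Ablation zero-fills a region set *after* standardization (zero is the
region's mean), removing its information with minimal distribution shift; an
alternative that refits standardization was rejected because it perturbs the
untouched regions too. The degradation statistic is the paired T over the k
per-fold differences (baseline − ablated) of the metric, df = k−1, positive
meaning degradation. Because network size alone moves this statistic,
significance is judged against a null of random same-size sets (default 300
iterations). Empirical p-values are one-sided toward degradation with an
add-one correction, $p = (1 + \#\{t_{null} \ge t_{obs}\})/(n+1)$, so p is
never 0 and calibrated p-values are uniform under a trait-free model (a
property the acceptance suite verifies by KS test). FDR control across one
analysis's hypothesis family uses Benjamini–Yekutieli by default, with
Benjamini–Hochberg available; the two sources inside the reference differ on
which one was used, so both are first-class options.

Degenerate cases are flagged rather than silently propagated: an empty set
yields t = 0 with flag `zero_delta`, and zero-variance nonzero deltas yield
a large capped t with flag `degenerate_variance`.

## Saliency

The saliency is the exact gradient of the scalar session output with respect
to the input, *with standardization inside the differentiable graph*. With
$z = (x - \bar{x})/s$ per region and $G = \partial N/\partial z$:

$$\frac{\partial N}{\partial x} = \frac{1}{s}\Big(G - \bar{G} - z\,\frac{\langle G, z\rangle}{T-1}\Big)$$

This forces per-region zero temporal sum and orthogonality to the
standardized data — both asserted to 1e-8 on every path. The BiLSTM
backward pass is hand-derived backpropagation through time; its agreement
with central finite differences (relative error below 1e-4 on small
instances) is the load-bearing correctness check for every downstream
saliency result. The ensemble saliency is the mean of member saliencies
(the ensemble output being the mean output), computed member-wise to bound
memory. The temporal band-pass is held fixed rather than differentiated
through: the filter is linear and the decimated input is already confined to
the band, so its Jacobian acts as the identity on admissible perturbations.

Per-region reliance is summarized by the saliency temporal variance
$\sum_t (\partial_{x_{it}} N)^2/(T-1)$ — the sample variance, since the mean
is zero by construction. Saliency-defined networks take, for each distinct
size among a reference partition's network sizes, the top-size regions by
training-fold mean saliency variance (ties broken by region order); sets are
nested by construction, and using training-fold saliencies keeps the
validation ablation free of circularity.

## Connectivity and innovation propagation

Perturbing standardized data along the saliency direction,
$X' = X + \eta D$, changes the correlation matrix to first order by
$\delta C = (D^\top X + X^\top D)/M$. We set $M = T-1$ everywhere — the
correlation normalizer, the standardization divisor and the
saliency-variance divisor are deliberately one constant, since the source
notation never reconciles its two normalizers. Aggregated across validation
subjects and sessions, pairs in the top 5% of $|\mathrm{mean}/\mathrm{SD}|$
are categorized by the sign of the underlying correlation versus the sign of
the change (IMPC/DMPC/DMNC/IMNC).

ZCA whitening factorizes standardized data as $X = ZW$ via the thin SVD
$X = USV^\top$: $Z = UV^\top$ (orthonormal innovations closest to the data)
and $W = VSV^\top$ (symmetric PSD; $W^2 = X^\top X$, a scaled square root of
the correlation matrix). Saliency propagates to the innovations through the
analytic SVD differential: with $P = U^\top D V$ and
$F_{ij} = 1/(s_j^2 - s_i^2)$ off-diagonal,
$dU = U(F \circ (PS + SP^\top)) + (I - UU^\top)DV S^{-1}$,
$dV = V(F \circ (SP + P^\top S))$, and $dZ = dU\,V^\top + U\,dV^\top$.
The formula is ill-conditioned when singular values nearly coincide
(relative gap below 1e-8); the implementation then warns and falls back to a
central finite difference of the whitening map, which is well-defined
because $Z$ itself is basis-invariant. A deterministic sign convention
(largest-magnitude entry of each right-singular vector positive) makes the
factor reproducible across platforms, though $Z$ and $dZ$ are invariant to
it. Finite-difference oracles, not a transcribed derivation, are the
authority for both propagation routes in the test suite.

## The synthetic generator

Each subject carries a latent trait $g$ (standard normal, with a
family-shared component weighted by a heritability of 0.5 so that
family-stratified CV is non-trivial). Confounds are
$c_j = \alpha g + \varepsilon_j$ with $\alpha$ chosen in closed form so the
population $R^2$ of $g$ on the confounds equals `confound_r2` (default
0.138, matching the shared variance reported for real confounds). Sessions
are stationary Gaussian series: innovations with covariance
$\Sigma(g) = \Sigma_0 + g \cdot \mathrm{effect\_scale} \cdot \Delta$ passed
through an AR(1) filter (coefficient 0.3). $\Sigma_0$ is a convex mix of the
identity and a normalized rank-5 factor structure (unit diagonal, smallest
eigenvalue ≥ 0.55, realistic mixed-sign correlations). $\Delta$ is a
symmetric Gaussian matrix supported on the salient region block (20% of
regions by default) with positive diagonal, normalized to unit spectral
norm, so positive-definiteness holds whenever
$|g| \cdot \mathrm{effect\_scale} < 0.55$; the rare more-extreme subject is
repaired by eigenvalue clipping with a warning.

`effect_scale` defaults to 0.22. The design rule, fixed before any model
training: the planted effect should give an FC-based ideal observer (the
elastic-net baseline on session-averaged RSFC) a cross-validated $R^2$ of
about 0.6 at the default testing scale (n = 300 subjects, 60 regions, 400
timepoints, 2 sessions), leaving clear headroom over the recurrent
ensemble's 0.3 recovery threshold. The test suite verifies that the
default scale of 0.22 puts the baseline's cross-validated $R^2$ in the
designed band.

What the generator does *not* emulate: hemodynamics, motion and
physiological artifacts, non-Gaussian and non-stationary dynamics, spatial
geometry, and any frequency structure beyond AR(1). Passing recovery tests
on this generator therefore demonstrates that the pipeline's machinery is
correct and sensitive to covariance-carried trait signal — not that the
architecture would attain any particular performance on real data. The
AR(1)-Gaussian choice is ours: it is the simplest process in which both the
connectivity propagation and the innovation-variance propagation carry trait
signal.

## Problem sizes and numerical choices

The test and acceptance suites run everything at desk scale, chosen as the
package's own testing conditions: the full-scale cohort is n = 300 subjects,
60 regions, 400 timepoints (51 after decimation), 2 sessions, 5-fold
family-stratified CV, 5-member ensembles with hidden size 16 trained 40
epochs (learning rate 3e-3, decay 0.3, crop 20, batch 16, gain 2, forget
bias 1); replicate studies of the saliency-network ablation use 10 cohorts
of the same size under 4-fold CV with 3-member ensembles of hidden size 10
trained 8 epochs, each compared against 10 size-matched random sets; the
null-calibration study uses a trait-free cohort (n = 48, 16 regions, 4
folds) with 200 observed draws, each judged against its own 50-iteration
size-matched null. The desk-scale learning rate sits above the full-scale
default because only a few hundred update steps fit in an epoch budget this
small.

Degenerate inputs error loudly and by name: zero-variance regions in
standardization and RSFC, rank-deficient confound designs, traits linear in
confounds, rank-deficient data in ZCA, unknown region labels in ablation.
Ties are always broken deterministically (region order in top-M selection,
lower tercile at edges). All reported empirical claims in this vignette are
recomputed by the test suite or the acceptance script; none are transcribed
from elsewhere.

## Known limitations

- The recurrent ensemble's absolute performance at desk scale (ensemble
  $R^2$ above 0.3 on the default synthetic cohort, as the acceptance suite
  verifies) is specific to the generator and not comparable to real-data
  figures.
- Gradient saliency is a local, first-order attribution; alternative
  attribution methods are out of scope.
- Ablation is zero-fill only; noise-injection or shuffling ablations are not
  implemented.
- Leave-one-family-out CV is not provided (computationally prohibitive for
  ensembles).
- The ZCA near-degeneracy fallback is approximate by construction; exactly
  repeated singular values make the individual factors (though not $Z$)
  non-unique.
- ZCA whitening and its saliency propagation require more (decimated)
  timepoints than regions; the default synthetic cohort (51 decimated
  timepoints, 60 regions) is outside that regime, so innovation-saliency
  analyses are exercised on longer-than-wide sessions.
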