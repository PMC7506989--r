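---
title: "Model-based essence features for sleep staging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based essence features for sleep staging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imbef)
```

# The problem

Sleep is scored by experts who label every 20- or 30-second window (epoch)
of a polysomnogram with one stage: wake (Awa), REM, and the non-REM depths
(S1–S4 under the older R&K rules, N1–N3 under the AASM rules, with N3
merging S3 and S4). Manual scoring of a full night is slow and somewhat
subjective, which motivates automatic scoring from a single EEG channel.

`imbef` implements a feature-based approach: each epoch is summarised by an
*improved model-based essence feature* (IMBEF) vector that fuses two
complementary descriptions of the epoch,

* **locality energies (LE)** — the energies of the epoch in the
  `2^l` equal-width sub-bands of a level-`l` wavelet-packet decomposition,
  a static description of where the power sits; and
* **dual state-space models (DSSM)** — the parameters of two
  innovation-form linear state-space models, one fitted to each of the two
  first-level wavelet-packet coefficient series of the epoch, a dynamic
  description of how each half-band evolves.

The fused vectors feed a bagged-tree classifier evaluated by 10-fold
cross-validation, with accuracy, Cohen's kappa and per-class sensitivity
computed from the pooled out-of-fold confusion matrix.

# Pipeline

## Preprocessing

The raw channel is low-pass filtered at 35 Hz (the usual artifact-rejection
band for sleep EEG) and cut into non-overlapping epochs of `te` seconds,
giving `j = te * fs` samples per epoch.

The filter deserves a note. A forward–backward (zero-phase) Butterworth
pass realizes the *squared magnitude* `1/(1 + (f/f_c)^(2N))` of the one-way
filter of order `N` (default 8). `lowpass_filter()` applies exactly that
response in the frequency domain rather than running a time-domain IIR
twice: time-domain forward–backward implementations leave edge transients
that visibly distort constant and near-DC segments, while the
frequency-domain realization is exactly linear, exactly zero-phase, and has
exactly unit DC gain — properties the test suite asserts at the 1e-9
level. The cost is that the convolution is circular; for multi-minute
recordings the wrap-around affects a negligible boundary region, and
epochs adjacent to the record edges are the only ones touched.

## Wavelet-packet decomposition and locality energies

`wpd_decompose()` expands the *full* packet tree: unlike the plain discrete
wavelet transform, both the approximation and the detail branch are split
at every level, so level `l` tiles 0–Nyquist into `2^l` equal sub-bands.
Three choices are fixed and documented because the transform's contracts
depend on them:

* **Boundary handling is periodization.** Every node at level `l` then has
  exactly `j / 2^l` coefficients and the analysis operator is exactly
  orthonormal, so total coefficient energy equals signal energy (asserted
  to 1e-8 across all 15 supported wavelets and levels 1–7). The price is
  the divisibility requirement `2^l | j`; the synthetic generator defaults
  to `fs = 128` Hz so that a 30-s epoch (j = 3840) divides by `2^7`.
* **Node order is natural (filter-bank) order**, node 1 being the repeated
  low-pass path. Locality energies are order-dependent, but any fixed
  order works because the classifier is order-agnostic.
* **The wavelet list is fixed** to the 15 candidates used by the grid
  searches: db1–db32 (selected orders), sym2/8/16, coif1/3, dmey. The
  first fourteen have exactly orthogonal filter banks. The discrete Meyer
  wavelet only admits FIR approximations; the widely circulated 62-tap
  filter is orthonormal only to ~1e-3, which would break the energy
  contract, so the package ships a 512-tap FIR sampled from the exact
  Meyer conjugate mirror filter (QMF deviation ~1.6e-9). Node splits are
  computed by FFT-based circular correlation, so the longer filter costs
  little.

`locality_energy()` then sums squared coefficients per node — the LE block
of the feature vector, `2^l_LE` non-negative numbers that scale exactly as
`c^2` when the epoch is scaled by `c`.

## Dual state-space models

The two level-1 coefficient series (low and high half-band, length `j/2`)
are each modelled by a scalar-output innovation-form state-space model

    u[k+1] = A u[k] + K e[k]
    y[k]   = B u[k] + e[k]

with `A` (n×n), output row `B` (1×n), steady-state Kalman gain `K` (n×1)
and white innovations `e`. `estimate_ssm()` implements the standard
output-only subspace (N4SID-family) estimator: mean removal, past/future
block-Hankel matrices of depth `horizon` (default `2n+1`), orthogonal
projection of the future onto the past row space (via QR), SVD truncated
at `n` giving the extended observability matrix and Kalman state sequence,
least squares for `A` and `B`, and the Kalman gain from the joint residual
regression `K = cov(state residual, innovation)/var(innovation)`. A CVA
(canonical variate) weighting was evaluated during development and gave no
measurable accuracy benefit on the validation family, so the plain SVD is
used.

Two design points resolve genuine ambiguities:

* **Canonicalization.** `(A, B, K)` is identified only up to a similarity
  transform, yet the raw entries are used as features. The estimator
  therefore fixes the basis deterministically: states are ordered by
  descending singular value and each left singular vector's
  largest-magnitude entry is made positive. The same series then always
  yields the same matrices, bit for bit. A corollary worth knowing: an
  overall sign flip of the epoch is absorbed by the sign convention, so
  the DSSM block (like the LE block) is invariant under `x -> -x`.
  Across *different* data realizations only similarity invariants
  (eigenvalues, prediction variance) are comparable, and the tests compare
  only those.
* **Degenerate inputs.** Series with relative standard deviation below
  1e-8 are rejected as zero-variance (a constant sub-band cannot be
  modelled); a requested order above the effective rank of the projection
  is rejected with the rank reported; a numerically exact fit clamps the
  innovation variance at a small positive floor.

On identifiability: recovering the eigenvalues of `A` from output data is
only well-posed when every mode is actually expressed in the output. If
the equivalent ARMA representation has a zero near a pole, no estimator —
including exact maximum likelihood — can recover that mode from moderate
samples. The estimator's recovery guarantees are therefore stated over a
family of damped resonances (complex-conjugate poles of modulus 0.8–0.95,
zeros confined to `|z| <= 0.3`), which is both well-posed and the
EEG-relevant regime (rhythmic band-limited activity); on that family the
observed worst eigenvalue error at T = 4000 was 0.026 over 50 trials, and
the asserted tolerance is 0.05.

## The IMBEF vector

`build_imbef()` concatenates `[LE block | DSSM block]`:
`2^l_LE + 2 (n^2 + 2n)` features per epoch. The selected operating point —
`db1` sub-bands with order-6 models, `db4` level-5 energies — gives the
default 32 + 96 = 128 dimensions. Feature names encode block and
parameter (`le_17`, `dssm2_A3.4`, …) for auditability. No feature
standardization is applied (trees are scale-equivariant; the discriminant
and SVM candidates receive the raw features too, keeping candidates
comparable).

## Classification and evaluation

Six candidate classifiers are wrapped behind one interface: linear and
quadratic discriminants, quadratic (degree-2 polynomial) SVM, 1-nearest
neighbour ("fine" KNN), bagged trees, and boosted trees with per-round
random undersampling (RUSBoost-style, a compact SAMME implementation over
`rpart` stumps-to-depth-5 trees). "Bagged trees" — the default and the
selected classifier — means bootstrap-aggregated unpruned decision trees
with *all* features considered at every split (pure bagging rather than a
random-subspace forest), 30 trees, realized via `randomForest` with
`mtry = p`.

`cross_validate()` draws `k = 10` folds uniformly at random (sizes differ
by at most one; stratification is available but off by default, matching
the plain protocol), trains on nine folds, predicts the held-out fold, and
pools all out-of-fold predictions into one confusion matrix. Reported
accuracy is trace/total of that pooled matrix (identical to the binary
TP/TN form at two classes); the per-fold mean is also returned, and the
two differ only marginally. Cohen's kappa uses the marginal-product chance
agreement, and sensitivity is the diagonal over the expert row sum.

## Grid search

Model selection mirrors a two-step procedure: `search_classifier()` jointly
scans classifiers × wavelets × orders on DSSM features *alone*;
`search_dssm_params()` is the same scan for a fixed classifier; then
`search_le_params()` scans LE wavelet × level with the DSSM block frozen.
Searches are exhaustive, cache features across candidates sharing them,
re-draw CV folds per candidate from `seed + candidate_index` (comparable
yet independent), record failures without aborting, and break ties by
higher kappa, then smaller order, then candidate-list order — preferring
simpler models deterministically. Full-scale grids (15 wavelets × 6 orders
× 6 classifiers on a whole database) are a batch job; the shipped tests
run the identical machinery on reduced grids in seconds.

# The synthetic generator

Real polysomnography databases cannot be redistributed with a package, so
`generate_stage_epochs()` provides labelled surrogate data: each epoch is
a sum of band-limited Gaussian noise components (delta/theta/alpha/beta,
realized with the same zero-phase Butterworth-magnitude filters as the
preprocessing module, so band-power oracles are self-consistent), an
optional component coloured by a user-supplied state-space model, and a 5%
white-noise floor, scaled to a stage-dependent amplitude.
`default_profiles()` encodes the canonical textbook contrasts: wake is
alpha/beta-dominant at moderate amplitude, REM and N1 are mixed-frequency
theta-leaning, N2 adds delta and spindle-range power, N3 is high-amplitude
delta-dominant. Sampling defaults are `fs = 128` Hz and `te = 30` s.

What the generator deliberately does **not** emulate: stage transitions
and temporal context (epochs are i.i.d. given the stage), K-complexes and
discrete spindles, artifacts (EMG, eye movements, electrode pops),
inter-subject variability, and scorer disagreement. Consequently the
synthetic stages are far more separable than real ones — the end-to-end
pipeline reaches essentially perfect cross-validated accuracy on 5 × 300
default-profile epochs, where real six-class sleep staging plateaus around
80–92%. Passing the synthetic suite therefore demonstrates that the
pipeline is *correct* (features carry the planted structure, the
classifier recovers it, shuffled labels collapse to chance), not that any
particular accuracy will be reached on real recordings.

Thresholds in the statistical tests were fixed by a single calibration run
and then frozen; each test file records the calibrated values next to the
assertion (e.g. DSSM-only 78.3% vs IMBEF 85.0% for the amplitude-contrast
experiment that shows the LE block adds information).

# Problem sizes and determinism

The shipped test suite uses 10-s epochs at 128 Hz for unit tests, the full
5 × 300 × 30-s configuration for the end-to-end check, T = 2000–6000 for
estimator recovery, and 100 epochs × 15 wavelets × 3 levels for energy
conservation — sizes chosen so the whole suite completes in about two
minutes on one core while still exercising every contract at meaningful
scale. Every stochastic step (generation, fold assignment, bootstrap,
undersampling, shuffling) flows from explicit integer seeds through an
RNG-state-preserving helper, so identical inputs give bit-identical
feature tables, reports and files; the reproducibility tests assert
byte-identical reruns end to end.

# Known limitations

* Single-channel only; no montage handling beyond picking one EDF channel.
* Epoch lengths whose sample count is not divisible by `2^l_LE` are
  rejected rather than padded; resample or choose a compatible
  level/epoch combination (a real 100 Hz × 30 s epoch supports levels up
  to 3 exactly).
* The EDF reader covers standard 16-bit EDF/EDF+ with one annotation
  track; exotic variants (logarithmic transducers, discontinuous EDF+D
  files) are out of scope.
* The subspace estimator targets stationary epochs; strongly transient
  epochs (movement time) should be excluded via the hypnogram mask, as
  scorers do.
* RUSBoost is a compact reimplementation, not a tuned reference; it exists
  to complete the candidate palette, and bagged trees remain the default.
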