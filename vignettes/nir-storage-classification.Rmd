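---
title: "Methods: fuzzy clustering of NIR spectra for storage-time classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy clustering of NIR spectra for storage-time classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirclust)
```

## The procedure and its assumptions

`nirclust` classifies high-dimensional FT-NIR diffuse reflectance spectra
by storage class without training a discriminative classifier: after
scatter correction and supervised dimension reduction, unsupervised fuzzy
clustering of the projected scores is matched against the known classes.
The pipeline assumes:

* spectra are absorbance-like vectors on a common, strictly decreasing
  wavenumber grid (cm⁻¹);
* scatter artefacts are affine per sample (`x ≈ b + a·r̄`), the model that
  multiplicative scatter correction (MSC) inverts exactly;
* class information is linear and low-rank: with `k` classes, at most
  `k − 1` discriminant directions carry the between-class structure;
* classes form compact (FCM/KHM) or ellipsoidal (GK) clusters in the
  reduced space.

### MSC

The reference ("standard") spectrum is the arithmetic mean of the training
spectra. Each sample is regressed on the reference by ordinary least
squares over all channels and corrected to `(x − intercept)/slope`. The
reference is fitted on the training split only and reused for the test
split; fitting it on all data is possible (`msc_scope = "all"`) but risks
leakage, so it is not the default. MSC with a mean reference is *not* the
identity on undistorted spectra when classes differ — the per-sample slope
deviates from 1 in proportion to the class contrast — so the two
preprocessing arms of the pipeline produce genuinely different (not merely
rescaled) score geometries; they are compared by their classification
results, not by score equality.

### OLDA

Classical LDA maximizes `trace(S_w⁻¹ S_b)`, which is undefined when the
within-class scatter is singular — always the case at 1557 channels and a
few hundred samples. The orthogonal variant maximizes the pseudo-inverse
criterion `trace((Gᵀ S_t G)⁺ (Gᵀ S_b G))` instead. The implementation
works entirely on factored forms: a thin SVD of the centered training
matrix (n × d; the d × d scatter matrices are never formed), whitening of
the class-mean factor in the total-scatter range, a second SVD for the
discriminant directions, and a final QR orthonormalization. Singular values
below `max(n, d) · eps` relative to the largest are treated as zero —
the standard pseudo-inverse threshold. Components are ordered by their
criterion contribution (the squared singular values of the whitened
class-mean factor); `component_shares` reports each retained component's
fraction. Column signs are fixed so each column's largest-magnitude entry
is positive, making score plots reproducible. When the between-class rank
is lower than the requested component count (e.g. exactly collinear class
means), the count is reduced with a warning rather than padded with noise
directions.

### Fuzzy clustering

All three estimators share one contract: user-supplied initial centers,
alternating membership/center sweeps, termination when the maximum absolute
center change drops below `tol` (`1e-5` by default) or after `max_iter`
(100) sweeps. One *iteration* is one full sweep, and convergence is checked
after it, so a fit initialized at a fixed point reports `n_iter = 1` —
this is the signature by which KHM, started from converged FCM centers,
terminates immediately on well-separated data. A membership-change
criterion is available via `conv = "memberships"`.

FCM uses the classical update `u_ik = [Σ_j (d²_ik/d²_jk)^{1/(m−1)}]⁻¹`
with squared Euclidean distances, the closed-form minimizer of the fuzzy
objective `Σ u^m d²` under the sum-to-one constraint; the objective is
non-increasing across sweeps by construction and the suite asserts it to
`1e-10`. KHM uses memberships `∝ d^{−p−2}` and the harmonic boosting
weights `w_i = Σ_l d_il^{−p−2} / (Σ_l d_il^{−p})²` in its center update;
its recorded objective is the harmonic-mean loss `Σ_i c / Σ_j d_ij^{−p}`.
GK replaces the Euclidean norm with per-cluster adaptive norms
`A_i = (ρ_i det F_i)^{1/q} F_i⁻¹` built from fuzzy covariance matrices
`F_i`; volumes `ρ_i = 1` throughout (no basis for unequal cluster volumes
here). Returned memberships are re-evaluated at the returned centers, so
`U`, `V` and `predict()` are mutually consistent.

Defaults follow the standard parameterization of this protocol: fuzzifier
`m = 2`, KHM power `p = 2`, `c = 6` clusters, `max_iter = 100`,
`tol = 1e-5`.

### Chained initialization and matching

FCM is seeded with the first sample of each class, in class order, of the
set being clustered; its converged centers initialize KHM and GK. Because
each seed comes from a distinct known class, cluster `i` corresponds to
class `i`, which justifies the default fixed-order cluster-to-class
matching. Synthetic benchmarks use optimal matching instead (exhaustive
over permutations, exact for `k ≤ 8`), since label recovery should not
depend on the seeding convention. Maximum-membership assignment breaks
ties toward the lowest cluster index (deterministic, documented).

## Numerical choices

* **Distance floor** `1e-12` on squared distances: all three membership
  formulas contain negative powers of distances; a sample at or within the
  floor of one or more centers has its membership split uniformly over the
  coincident centers and zero elsewhere.
* **GK regularization**: `F_i ← (1 − γ) F_i + γ (det F_i)^{1/q} I` with
  `γ = 1e-6`, then an eigenvalue floor capping the condition number at
  `1e10`. Raw GK is numerically fragile on near-collinear score clouds
  (covariances of ~20 points in 5 dimensions); the blend preserves the
  determinant scale while the floor guarantees invertibility. Setting
  `γ = 1` forces an identity-shaped norm, making GK coincide with FCM
  exactly — the suite asserts equality to `1e-8`.
* **Degenerate MSC slopes** (`|a| < 1e-8`) leave the sample uncorrected
  with a warning rather than dividing by ~0.
* **Cluster collapse** (a cluster's total membership mass at numerical
  zero) raises an error naming the cluster rather than silently producing
  NaN centers.

## The synthetic generator

Real storage-study spectra are rarely deposited, so the generator
emulates their structure: a quadratic baseline; Gaussian absorption peaks
at 5200 and 6900 cm⁻¹ (widths 120/220 cm⁻¹) whose amplitudes grow linearly
with storage class (`class_amplitude_step`, absorbance units per class);
per-sample affine scatter (`slope ~ 1 + N(0, 0.05)`,
`offset ~ N(0, 0.02)`); i.i.d. channel noise (`noise_sd = 0.01`) tripled
inside the 4000–4350 cm⁻¹ water band. Draw order (slopes, offsets, noise;
class-major) is fixed, so a seeded dataset is bitwise reproducible.

The default step `c(0.0175, 0.0125)` was calibrated once to the regime the
protocol is designed for: end-to-end accuracy in the high-80s/low-90s with
confusion confined to adjacent days, while day 1 and day 6 are essentially
never crossed. The `well_separated_config()` preset (step `c(0.02, 0.015)`,
`noise_sd = 0.008`) makes all six classes cleanly recoverable (97–100%
across seeds) and is used wherever a test needs an unambiguous generating
partition. Its noise is moderate rather than tiny on purpose: the
generator's class means are exactly collinear (linear amplitude growth), and
vanishingly tight clusters on a line make the harmonic-means objective
sharply multimodal — a numerical artefact of the idealized geometry, not a
property of real spectra, which would obscure what the
initialization-robustness tests are meant to show.

What the generator does **not** emulate: correlated (pink) instrument
noise, nonlinear baseline drift, wavelength-dependent scatter, within-class
biological covariance, or any chemistry linking storage day to specific
band shapes. Class means are exactly collinear here, whereas real
storage trajectories curve through spectral space. Passing tests therefore
demonstrate correctness of the estimators and the protocol's plumbing —
not that real pork spectra of six storage days are 90% separable.

## Problem sizes

The test suite and acceptance script run the full-sized protocol
(402 × 1557 spectra, 270/132 split, 5 components) a handful of times and
scale everything else down (3-class, 120-channel configs; ≤ 200-point
clustering instances), keeping the default suite around half a minute on
one CPU.

## Known limitations

* Optimal matching is exhaustive over permutations and limited to 8
  clusters (exact and fast at the protocol's `k = 6`).
* OLDA assumes classes are linearly separable in the projected space; no
  kernel or PLS variants are provided.
* The KHM initialization-insensitivity property is a statistical tendency,
  not a theorem: at `p = 2` a minority of dataset realizations retain KHM
  local optima ~10% above the global objective for some random
  initializations.
* GK with six clusters of ~22 points in 5 dimensions leans on the
  covariance regularization; with substantially fewer points per cluster
  it will (by design) stop with a collapse error.
```{r session}
sessionInfo()
```
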