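---
title: "Methods: simulating and scoring M/EEG source-estimate fidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring M/EEG source-estimate fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourcefidelity)
```

This vignette is the package's own account of its models and of the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` do not themselves
compute.

## The evaluation model

The sensor signal of an active source distribution is `y_t = G x_t`, with
`G` the gain (lead-field) matrix. A linear estimator applies an inverse
kernel, `x̂_t = K y_t`, so `x̂_t = K G x_t = R x_t`: the resolution matrix
`R = KG` fully characterizes noiseless linear estimation. Two things it
cannot characterize are robustness to noise and nonlinear estimators. The
package therefore simulates: each patch `P_j` of a disjoint parcellation is
activated uniformly (`X[k, t] = amplitude` for `k ∈ P_j`, constant over
time), data `Y = αGX + N` are formed, the estimator is run, and the
absolute estimate is averaged per patch and time into the empirical
resolution matrix `R̂`. For a linear estimator at infinite SNR, `R̂` must
equal the patch-reduced analytic `R`; the test suite asserts this to 1e-10
relative Frobenius error, which validates the simulation plumbing
end to end.

### SNR control

`α` is chosen so that the *mean amplitude SNR across patch activations and
sensor modalities* equals the requested value: per modality, the RMS sensor
amplitude of each patch's signal is averaged over patches and divided by
that modality's noise RMS; `α` is the target divided by the mean of the
modality ratios. Activation amplitudes themselves are never changed —
rescaling them per patch would be physiologically unrealistic and would
obscure the spatial variability of estimator performance. The amplitude
convention (RMS rather than power) makes the SNR axis an amplitude SNR.
Two limits get special treatment: `snr = Inf` omits the noise term exactly,
and `snr = 0` keeps the noise and sets `α = 0`, matching the "no signal"
and "no noise" end points of an SNR axis.

## Synthetic fixtures: what they emulate, and what they do not

* **Source space.** A spherical Fibonacci lattice with seeded tangential
  jitter, radially perturbed by a smooth low-order random field
  (`radius · (1 + bumpiness · f)`, default radius 0.08 m, bumpiness 0.1).
  Orientations are outward normals of the perturbed surface. `bumpiness > 0`
  is the default deliberately: purely radial dipoles are magnetically
  silent in spherically symmetric geometries and would confound fidelity
  scores. The *unperturbed* sphere plays the role of an inflated reference
  surface; patch centers of gravity are computed there, which only requires
  a smooth one-to-one inflation.
* **Parcellation.** Seed directions are chosen by farthest-point sampling
  of the dipole directions themselves (seeded start), and each dipole joins
  its nearest seed, ties to the lowest patch index. This guarantees
  non-empty patches, tiles the sphere quasi-uniformly (the synthetic
  analogue of an anatomical atlas with roughly equal-area labels), and
  degenerates gracefully to one-dipole patches when as many patches as
  dipoles are requested. Patches smaller than
  `min(4, floor(n_sources/n_patches))` are merged into neighbors, emulating
  atlas labels whose sizes range from a few to a few dozen dipoles.
* **Forward model.** Free-space current-dipole fields
  (`B = (μ₀/4π)(q × d)/|d|³`) projected on radial magnetometer axes;
  planar-gradiometer-like rows as field differences across a 16.8 mm
  tangential baseline; EEG-like rows as the potential in an unbounded
  homogeneous conductor (σ = 0.3 S/m). This is a deliberate simplification:
  no volume currents, no multi-shell head. The evaluation framework itself
  is agnostic to forward-model realism — it scores an estimator *given* a
  gain matrix — but absolute error magnitudes from these fixtures must not
  be read as predictions for real head geometry. The default fixture is
  single-modality magnetometers; multi-modality arrays are exercised where
  the per-modality SNR averaging itself is under test.
* **Noise.** Low-rank spatially mixed AR(1) factors plus a white sensor
  floor. The default mixing uses randomly drawn gain columns (amplitude
  10 nAm, 20 factors, AR coefficient 0.95, floor 10 % of mixed power), so
  the noise has the spatial signature of background *brain* activity seen
  through the forward model — the dominant component of resting-state
  M/EEG — with exactly two knobs and no real data. Artifacts (cardiac,
  ocular), sensor drifts and environmental interference are not modeled.
* **Epoch bookkeeping.** Resting noise is cut into 135 epochs of 0.5 s at
  1000 Hz; 49 seeded randomly drawn epochs form the evoked pool whose
  windowed average is the noise `N` added to each 100 ms activation; the
  held-out 86 estimate the covariance `C` used by the estimators. The
  100 ms windows are drawn at a seeded random offset within each epoch
  rather than time-locked, avoiding epoch-boundary artifacts.

Consequently, a passing suite demonstrates the *structural* claims —
convergence of `R̂` to `R`, exact zero localization of standardized
estimators on noiseless point sources, monotone improvement with SNR, the
sigmoidal AUROC(SNR) shape, the focality of the mixed-norm estimate — but
not absolute error magnitudes, per-region topographies, or fractions that
depend on real cortical geometry and sensor layouts.

## Estimators and numerical choices

All estimators use fixed-orientation dipoles and no depth weighting.

* **MNE**: `K = Gᵀ(GGᵀ + λ²C)⁻¹` via Cholesky solve; no explicit inverse.
* **dSPM / sLORETA**: diagonal standardizations of the MNE kernel by the
  mapped noise energy and the resolution diagonal respectively. Both
  weights are scale-free in the data.
* **eLORETA**: the weight update is implemented with a square root,
  `d_i = √(g_iᵀ M⁻¹ g_i)/x₀` with `x₀ = 1 A·m`. Unit analysis forces this:
  `[D] = 1/(A·m)²` requires `d_i` to scale linearly with the gain, which
  the square of the quadratic form would violate. The choice is verified
  behaviorally — with the root, the converged kernel has the exact
  zero-localization property for noiseless point sources (a
  Cauchy–Schwarz argument that holds for any positive-definite `C` and any
  `λ²`), which the test suite asserts column by column. Initialization
  `d = 1`, relative-change stopping at 1e-6, cap 100 iterations;
  non-convergence is a warning with status, not a failure.
* **MxNE**: FISTA on `½‖Ỹ − G̃X‖²_F + α Σᵢ‖X_{i,:}‖₂` in the whitened
  domain (`G̃ = C^{-1/2}G`), step `1/L` with `L` the largest squared
  singular value, block soft-threshold prox, stopping on relative objective
  decrease < 1e-6 with a 3000-iteration cap (defaults). `α` is expressed as
  a percentage of `α_max = maxᵢ‖g̃ᵢᵀỸ‖₂`, the smallest value that zeroes
  every row (default 55 %; 100 % returns exactly zero). The whitening and
  `α_max` conventions are verified by Karush–Kuhn–Tucker tests — active
  rows have residual correlation `α` to 1e-3 relative, inactive rows at
  most `α` — rather than assumed to match any particular reference
  implementation bit for bit.

### Regularization scale

The conventional coupling `λ² = SNR⁻²` presumes gain and noise covariance
on a common scale. In physical units they are not: gain entries are fields
*per unit dipole moment* while the covariance is squared *field*, so
`λ²C` would be numerically invisible next to `GGᵀ`. The pipeline therefore
rescales the estimated covariance so that `tr(C) = tr(GGᵀ)`
(`balance_covariance()`), equating unit-source signal power and noise
power, before building kernels. This is what makes `λ²` behave as a
dimensionless knob — including the documented limit in which dSPM and
sLORETA converge to the same estimate as `λ² ≫ 1`, asserted at `λ² = 10⁶`.
The kernel constructors themselves apply the textbook formulas to whatever
covariance they are given, so the closed-form scalar identities hold
exactly when balancing is off. At `snr = 0` the coupling would give
`λ² = ∞`; the pipeline substitutes `λ² = 10⁶` (deep in the dSPM = sLORETA
regime) with `α = 0`.

## Metrics

* **PE**: Euclidean distance from the patch's center dipole (member closest
  to the spherical-surface center of gravity, ties to the lowest index) to
  the amplitude argmax (ties to the lowest index). 3-D distances are used,
  not geodesics — a documented limitation, since small 3-D errors can cross
  sulcal walls.
* **SD**: estimate-weighted ℓ₁ mean distance from the peak dipole (the ℓ₁
  choice mitigates outlier influence relative to ℓ₂).
* **E_cg**: center-of-gravity error, provided for comparison only; on a
  surface source space the centroid is biased toward the head center, so
  superficial sources show inflated values.
* All-zero estimates (common for MxNE under strong regularization) have no
  peak: PE/SD are `NA`, excluded from medians, and their fraction is
  reported as a statistic (`zero_frac`) — sparsity is a property of the
  estimator, not an error.
* **ROC/PRC**: the column-normalized `R̂` is thresholded on a grid of 1001
  evenly spaced values in [0, 1] (fine enough that trapezoid error on the
  fixtures is far below the assertion tolerances; the grid density is a
  package choice, documented and oracle-tested). Classification uses the
  strict inequality `R̃ > T`, so ties at exactly `T` are inactive —
  determinism where the defining inequalities leave equality unassigned.
  TP/FP/TN/FN come from the diagonal/off-diagonal split; the ROC curve is
  augmented with (0, 0) and (1, 1); at thresholds with no positives the
  undefined PPV copies the value at the highest threshold below 1 that has
  positives (horizontal-asymptote convention); areas are trapezoidal over
  the realized points without extra interpolation.
* **Sigmoid fit**: `AUROC(SNR) = a·tanh(b·log₁₀SNR + c) + d` by
  Levenberg–Marquardt least squares, canonical start
  `(0.25, 1, 0, 0.75)` plus two seeded multistarts, best residual sum kept;
  SNR = 0 and ∞ are excluded (log undefined); a constant response returns a
  flat fit with `r² = 0` instead of failing.

## Experiment orchestration

`run_experiment()` sweeps virtual subjects × estimators × SNR grid. A
virtual subject is an independently seeded geometry/noise realization;
medians over patches are aggregated across subjects as mean ± standard
error (`sd/√n`), the same role per-subject medians play in group-level
reporting. Cells persist as JSON when an output directory is configured and
identical configurations reuse existing cells. Everything derives from
`base_seed`; reruns are bit-identical.

The default problem sizes — 600 sources, 60 patches, 64 sensors, 3 virtual
subjects — are the package's desk-scale operating point: large enough that
patches average 10 dipoles and the sensor count is realistic for a
single-modality array, small enough to iterate on interactively. Scaling to
an atlas-sized setup (tens of thousands of sources, ~1000 patches) is a
configuration change, not a code change.

## Known limitations

* Free-space dipole fields ignore volume currents; EEG-like rows use an
  unbounded homogeneous conductor. Absolute gain structure differs from
  BEM-based models.
* Single-patch activations only; the combinatorics of simultaneous
  activations (`configuration_count()`) are computed but multi-source
  simulation, correlated waveforms and the corresponding redefinitions of
  PE/SD are out of scope.
* Euclidean, not geodesic, distances in PE/SD.
* No beamformers: they presuppose volumetric source models and
  forward-model sensitivity analyses that this surface-patch framework
  would bias against.
* Amplitude-reconstruction accuracy is not scored; estimators returning
  dimensionless statistics (dSPM, sLORETA) make it ill-defined across
  methods.
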