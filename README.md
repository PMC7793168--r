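# sourcefidelity

Quantifying the spatial fidelity of MEG/EEG distributed source estimates.

Magneto- and electroencephalography record a few hundred sensor channels
generated by thousands of candidate cortical current sources, so any source
estimate is a heavily regularized solution of an ill-posed inverse problem.
How well an estimator localizes activity — and how that degrades with noise —
is an empirical question. `sourcefidelity` implements a simulation framework
for answering it: it activates one cortical patch at a time, pushes the
signal through a forward model, superposes structured resting-state noise at
a controlled signal-to-noise ratio, reconstructs the sources with a chosen
estimator, and scores the reconstruction. It is aimed at methods developers
and at experimentalists deciding which estimator (and how much averaging)
a study needs.

Everything runs on fully synthetic fixtures — a quasi-uniform spherical
source space with a disjoint patch parcellation, a free-space current-dipole
forward model and a low-rank AR(1) noise model — so the whole pipeline is
self-contained, seeded and fast. User-supplied gain matrices, source-space
tables and noise epochs in delimited text formats are accepted at every
module boundary.

## The framework

For a linear estimator with inverse kernel **K** and gain matrix **G**, the
**resolution matrix** **R** = **KG** maps true sources to estimates
(x̂ = **R**x); its columns are point-spread functions. Because **R** exists
only for linear, noiseless estimation, the package's central object is the
**empirical resolution matrix** R̂: patch j is activated uniformly at
10 nAm for 100 ms, sensor data Y = αGX + N are formed with evoked-average
noise N and a scaling α that fixes the mean amplitude SNR across patch
activations and sensor modalities, and

  R̂\[i, j\] = Σₜ Σ_{k∈Pᵢ} |X̂\[k, t\]| / (nₜ |Pᵢ|),

the patch-i mean absolute estimate under activation of patch j. At infinite
SNR and a linear estimator, R̂ equals the patch-reduced analytic **R** —
a built-in verification of the simulation.

Implemented estimators:

* **MNE** — K = Gᵀ(GGᵀ + λ²C)⁻¹, Tikhonov-regularized minimum norm with
  noise covariance C and λ² = SNR⁻²;
* **dSPM** — MNE standardized by the mapped noise energy,
  wᵢ = 1/√(KCKᵀ)ᵢᵢ;
* **sLORETA** — MNE standardized by the resolution diagonal,
  wᵢ = 1/√(KG)ᵢᵢ;
* **eLORETA** — iteratively determined diagonal depth weights,
  dᵢ = √(gᵢᵀM⁻¹gᵢ)/x₀ with M = GD⁻¹Gᵀ + λ²C, giving exact zero
  localization error for noiseless point sources;
* **MxNE** — the nonlinear ℓ₂,₁ mixed-norm estimate, solved by FISTA with a
  block soft-threshold prox in the whitened domain, with the regularization
  expressed as a percentage of α_max (default 55).

Scoring: per-patch **peak localization error** PE (distance from the patch
center to the amplitude peak), **spatial dispersion** SD (estimate-weighted
ℓ₁ mean distance from the peak), center-of-gravity error, and a
threshold-sweep classifier analysis of the column-normalized R̂ giving
ROC/PRC curves, AUROC and AUPRC, plus the sigmoidal model
AUROC(SNR) = a·tanh(b·log₁₀SNR + c) + d fitted across an SNR grid.

## Worked example

```r
library(sourcefidelity)

space   <- build_sphere_source_space(300, radius = 0.08, bumpiness = 0.1, seed = 1)
parc    <- parcellate(space, 30, seed = 1)
sensors <- sphere_sensor_array(48, radius = 0.12, seed = 1)
gain    <- build_gain(space, sensors)
model   <- brain_noise_model(gain, seed = 1)
epochs  <- simulate_epochs(model, n_epochs = 135, duration = 0.5, seed = 1)

er <- empirical_resolution("sLORETA", space, parc, gain, epochs, snr = 3, seed = 2)
#> <empirical_resolution> sLORETA, 30 patches, SNR = 3, alpha = 0.356, seed 2

fm <- fidelity_metrics(er, space, parc)
head(fm, 3)
#> # A tibble: 3 x 7
#>   patch  size center     pe     sd    ecg zero_estimate
#> 1     1    16     17 0.0260 0.0790 0.0490 FALSE
#> 2     2    13     24 0.0176 0.0747 0.0486 FALSE
#> 3     3    11     26 0.0218 0.0806 0.0507 FALSE

roc_prc(er)
#> <roc_prc> 30 patches, 1001 thresholds, AUROC = 0.9993, AUPRC = 0.9219
```

At SNR = 3 on this 300-dipole fixture, sLORETA localizes the median patch
to within 18 mm of its center (`median(fm$pe)`), spreads the estimate over
a weighted mean distance of 83 mm (`median(fm$sd)`), and classifies
active/inactive patches nearly perfectly (AUROC 0.9993). The signal was
multiplied by α = 0.356 to hit the target mean SNR.

A full sweep over virtual subjects and an SNR grid, with the sigmoid fit:

```r
cfg <- experiment_config(methods = "MNE", snr_grid = c(0.01, 0.1, 1, 3, 10),
                         n_subjects = 2)
ex <- run_experiment(cfg)
ex$summary[, c("method", "snr", "pe", "sd", "auroc")]
#>   method   snr     pe     sd auroc
#> 1 MNE     0.01 0.117  0.106  0.513
#> 2 MNE     0.1  0.0542 0.105  0.706
#> 3 MNE     1    0.0142 0.0887 0.991
#> 4 MNE     3    0.0133 0.0786 0.998
#> 5 MNE    10    0.0128 0.0679 0.998

ex$fits$MNE
#> <sigmoid_fit> AUROC(SNR) = 0.244 tanh(2.310 log10 SNR + 2.110) + 0.754, r2 = 1.000
```

Localization error and dispersion fall monotonically with SNR — near random
guessing at SNR = 0.01, near ceiling above SNR = 3 — and AUROC follows a
clean sigmoid in log₁₀ SNR. `autoplot()` methods are provided for empirical
resolution matrices, ROC/PRC curves, sigmoid fits and sweep summaries;
`tidy()`/`glance()` tidiers for the fitted objects.

A thin command-line front end with `fixture`, `resolution`, `metrics`,
`sweep` and `report` subcommands lives in `inst/cli/sourcefidelity`.

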