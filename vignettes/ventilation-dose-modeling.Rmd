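---
title: "Ventilation-weighted dose features and RP prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventilation-weighted dose features and RP prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpvent)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions behind them, the numerical choices made where a
published description is silent, and what a green test on synthetic data
does and does not establish.

## 1. The ventilation model

Both ventilation metrics estimate the voxelwise *specific volume change* of
lung tissue between peak exhalation and peak inhalation, taking as given a
deformable registration whose displacement field `u(x)`, in millimetres on
the exhale (fixed) grid, points each exhale voxel to its corresponding
location in the inhale (moving) image. That direction convention is the only
one under which the registered inhale intensity `HU_in{x + u(x)}` is
well-defined on the exhale grid; the package asserts it rather than
guessing from data.

**HU metric.** Lung CT intensity is modelled as a linear mixture of air
(−1000 HU) and tissue (0 HU). A voxel's air fraction changes with local
inflation, giving

    V_HU(x) = ( HU_ex(x) − HU_in{x+u(x)} ) / ( HU_in{x+u(x)} + 1000 ).

The registered inhale image is produced by `resample_inhale()` with
trilinear interpolation; sample points outside the inhale volume take the
air padding value −1000 HU and are flagged in a validity mask rather than
silently used.

**Jacobian metric.** The same quantity measured geometrically:
`V_Jac = det(I + ∇u) − 1`, the relative volume change of the deformation.
Derivatives are central finite differences scaled by voxel spacing,
one-sided on the volume faces. Central differences are *exact* for affine
fields, which the test suite exploits: any linear field is an oracle with a
constant closed-form answer. For the radial Gaussian-bump family
`u = a·exp(−r²/2s²)(x−c)` the closed form is
`det = (1+g)²(1+g − (r²/s²)g)` with `g = a·exp(−r²/2s²)`; the measured
truncation error of the finite-difference route against this closed form is
approximately `1.8·a·h²/s²` (verified by grid refinement, second order in
the spacing `h`). The oracle suites are therefore run at parameter
combinations where that bound sits below the asserted tolerance — e.g.
1e−3 at `h` = 1 mm requires bump widths `s` ≳ 14 mm at amplitudes up to 0.1.
The sinusoidal family, whose closed form is also recorded, exercises the
same bound with a less benign spectrum.

**Percentile conversion.** Ventilation magnitudes are not comparable across
patients (they depend on breathing depth), so each patient's valid in-mask
values are rank-transformed to percentiles, `100·rank/N`, ties receiving
the mean rank of their group. Two choices a published description typically
leaves open are fixed here: the conversion is *per patient* (not pooled
across a cohort), computed *over the evaluation mask after exclusions*, so
that the DFH weights and the DVH denominators refer to the same voxel set;
and negative ventilation values (possible with noisy registration) are
ranked as-is rather than clipped — they are simply the lowest function
percentiles. The resulting map is uniform up to ties, lies in (0, 100], and
is invariant under any strictly increasing transform of the input — a
property the tests assert, since it is what makes the HU- and
Jacobian-metric DFH features comparable.

**Near-air guard.** The HU metric divides by `HU_in_reg + 1000`, which
vanishes on pure air. Voxels with `|HU_in_reg + 1000| < 50` HU are excluded
from the ventilation map and the evaluation mask (threshold configurable).
The value 50 HU keeps the denominator bounded away from zero while retaining
emphysematous parenchyma around −950 HU.

## 2. Dose features

Physical dose is first converted voxelwise to EQD2 under the
linear-quadratic model with `α/β = 3` Gy (lung late effect):
`EQD2 = D·(d + α/β)/(2 + α/β)`, with per-voxel fraction dose
`d = D/n_fractions` — the fraction *count* is uniform, the fraction *size*
varies spatially. The conversion is the identity exactly at 2 Gy/fraction
and strictly increasing in dose, both asserted. Fraction sizes outside the
1.8–3.0 Gy regime the feature definitions assume trigger a warning only.

DVH features are computed on the healthy-lung evaluation mask (lungs minus
GITV minus the airway/vessel exclusion): `MLD` is the in-mask mean EQD2;
`Vx` the percentage of in-mask voxels with dose *strictly exceeding* x Gy
(x = 5, 10, 20, 30, 40, 50) — strict, because the feature is defined as
volume "exceeding" the threshold. DFH features weight the same reductions
by the percentile function map:
`fVx = 100·Σ_{D>x} f_v / Σ f_v`, `fMLD = Σ f_v·D_v / Σ f_v`. With a
uniform map these collapse to the DVH features exactly (to 1e−12 in the
tests), which is the key internal consistency check between the two feature
families.

GITV position is the tumor centroid normalized to the lung bounding box per
axis, clipped to [0, 1], with the convention 0 = superior, anterior, left
(array index 1 on each axis). The zero end is a documented convention, not
derivable from the feature definition; flipping it only reflects the
feature, which matters to no rank-based downstream statistic.

## 3. The modeling protocol

The experiment protocol in `run_experiment()`:

* **Splits.** `n_repeats` (default 50) independent stratified splits,
  `round(0.7·class size)` of each class to training (half-up rounding).
  Within a repeat, all feature sets — and, in `run_pipeline()`, both
  ventilation metrics — see the identical split, so comparisons are paired
  by repeat.
* **Standardization.** Features are z-scored with training-partition
  moments only (population SD, denominator N); constant training features
  are dropped from both partitions with a warning. Fitting the scaler on
  the full table would leak test information into the model; the tests
  assert the scaler is invariant to the test partition.
* **Hyperparameters.** `C` and `γ` of the RBF-SVM maximize mean AUC over
  stratified 5-fold inner CV of the training partition, searched by a
  Gaussian-process surrogate with expected-improvement acquisition over a
  log-uniform box `C ∈ [1e−3, 1e3]`, `γ ∈ [1e−4, 10]`, 30 evaluations of
  which the first 8 are a seeded Latin hypercube. The box, budget and GP
  constants (squared-exponential kernel, lengthscale 0.2 on the unit
  square, noise 1e−3 matching the fold-to-fold variance of a mean of five
  AUCs) are configurable via `tune_control()`; published descriptions of
  such tuners rarely state them, so reproducibility was preferred over
  fidelity to unstated settings. The SVM itself is a standard C-SVC dual
  solved by SMO with maximal-violating-pair selection (compiled code).
* **Scoring.** AUC is computed from decision-function margins, not
  calibrated probabilities — AUC is rank-based, so calibration cannot
  change it. Ties count one half.
* **Statistics.** Paired feature-set comparison: two-sided Wilcoxon signed
  rank on per-repeat test AUCs, zeros dropped, exact null for ≤ 25
  informative pairs, tie-corrected normal approximation beyond; all
  differences zero returns p = 1 with a warning. Per-feature screening:
  two-sided Mann-Whitney U. Redundancy: Spearman correlation, tie-corrected,
  with constant columns flagged as undefined rather than silently zeroed.
* **Seeds.** One master seed deterministically derives the per-repeat split
  seeds, inner-fold seeds and optimizer seeds; the whole experiment is
  bit-reproducible, which the pipeline tests verify at the CSV level.
* **Imbalance.** At ~25% incidence, stratification alone preserves the
  class ratio in every partition; no class weighting is applied, since the
  protocol being emulated used none.

Two summary ambiguities are resolved by reporting both candidates:
`summary()` gives the IQR and the half-IQR (quartile deviation), and both
percentile and normal-theory 95% intervals of the test AUC across repeats.

The number of repeats deserves a note: a protocol described as "50 models
(10 times of cross-validation)" admits several readings; this package
implements `n_repeats` independent stratified 70/30 splits with a default
of 50, which reproduces the reported model count and keeps every repeat
exchangeable.

## 4. What the phantom generator emulates — and what it does not

The generator exists because cohorts of this kind (planning CT, DIR fields,
dose grids, toxicity grades) are essentially never deposited. It emulates
the *structural assumptions* the analysis relies on, with every default
chosen once, up front:

* **Geometry.** Two ellipsoidal lungs in a 28×28×32 grid at 7 mm spacing
  (≈2 L total lung, desk-scale), a spherical GITV of 12–25 mm radius placed
  uniformly in the central lung bounding box, and a midline cylinder
  standing in for the trimmed central airways.
* **Deformation.** Per-lung radial Gaussian expansion (amplitudes
  0.05–0.13, widths 55–85 mm → specific ventilation up to ≈0.5, the
  physiological range), a small sinusoidal wiggle, and a tumor-centred
  radial component whose signed amplitude is the `function_dose_overlap`
  knob: positive overlap concentrates high function where the dose is.
* **CT pair.** The inhale image is a smooth parenchyma field around
  −880 HU (bounded in −940…−820 HU so the near-air guard never fires on
  phantom tissue); the exhale image is constructed by *inverting the HU
  metric* at the field's own Jacobian ventilation,
  `HU_ex = HU_in_reg + V·(HU_in_reg + 1000)`. This guarantees an exact
  ground truth — the HU metric must recover `V` to interpolation round-off,
  and the two metrics must agree voxelwise — at the deliberate price of
  realism: testability was chosen over simulating density change
  independently.
* **Dose.** Prescription dose inside the GITV with Gaussian falloff
  (σ = 20 mm) beyond its surface; prescriptions are drawn from the four
  reference fractionation schemes (60 Gy/30, 66/33, 69/23, 72/24) at their
  printed cohort proportions. This is a stand-in for treatment-planning
  dose, not beam transport.
* **Labels.** A logistic model on cohort-z-scored features; the
  demonstration default loads 2 SD units on fV20 — a strong, recoverable
  effect — with the intercept auto-calibrated by root-finding so the
  expected incidence matches the 24.7% of the reference cohort. At small n
  a degenerate all-one-class draw is repaired by deterministically flipping
  the most extreme-probability patient, so stratified modeling remains
  possible.

Not emulated: CT texture and noise, respiratory-phase sorting artifacts,
reconstruction, registration error, anatomical lung shape, heterogeneous
tissue densities, or any beam physics. Consequently a green modeling test
establishes that the *pipeline* recovers structure the generator put in —
it says nothing about clinical predictive performance, and the package
makes no such claim. Headline numbers from an undeposited clinical cohort
cannot be reproduced here and are not asserted anywhere in the tests.

## 5. Numerical choices and degenerate inputs

* Excluded voxels carry `NA` sentinels and are dropped from masks, never
  imputed.
* `resample_inhale` pads out-of-volume samples with −1000 HU and returns a
  validity mask; degenerate fields (everything outside) yield an all-false
  mask, not an error.
* Percentile ties: mean tie rank (deterministic; all-equal input maps to a
  single mid-percentile).
* Linear fields with `det(I + A) ≤ 0` (non-invertible deformation) are
  rejected at construction with the determinant in the message.
* Unphysical CT construction (exhale pushed to ≤ −1000 or ≥ +200 HU) is
  rejected rather than clipped.
* Splits that would empty a partition or a class, inner folds that cannot
  contain both classes, empty evaluation masks, zero total function weight,
  and single-class AUC inputs are all hard errors with diagnostics.
* SMO: stopping tolerance 1e−3 on the KKT violation, iteration cap 1e5;
  offset from free support vectors, midpoint of the feasible interval if
  none.

## 6. Known limitations

* The phantom's dose and anatomy are analytic idealizations; effect sizes
  chosen for the label model are demonstration-scale, and the signal
  recoverable at n = 100 phantoms should not be read as a clinical effect
  size.
* The Bayesian optimizer is a fixed-hyperparameter GP-EI loop; it is
  deterministic and adequate for a 2-D box with a 30-evaluation budget, not
  a general-purpose optimizer.
* Clinical geometry features of the phantom (GITV position/volume) are
  correlated with the dose-function features by construction — as they are
  in patients — so the "clinical-only" feature set is not a pure noise
  floor in phantom experiments.
* DICOM-RT ingestion and deformable registration itself are out of scope;
  the displacement field is an input, and volume I/O beyond the in-memory
  containers and CSV/JSON artifacts is a documented extension point.
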