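---
title: "Parametric response mapping: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric response mapping: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmap)
```

## The problem

Mean-value readouts of a serial imaging study (mean tumor ADC, mean
peritumoral HU) dilute spatially heterogeneous treatment response: a lesion
whose core responds while its rim progresses can show no net change.
Parametric response mapping avoids that by classifying each voxel of a
co-registered scan pair individually against a *no-change* interval, and
summarizing the lesion by the volume fractions of increased, decreased and
unchanged voxels (PRM₊ / PRM₋ / PRM₀).

The package covers the full chain: quantitative map generation (ADC from
two-b-value DW-MRI; Hounsfield-calibrated CT), longitudinal registration,
threshold calibration from test–retest data, voxel classification with
summaries and overlays, and the trial-level statistics (PSA response
calls, growth delay, group comparisons) that connect the imaging biomarker
to clinical outcome.

## Models and assumptions

### ADC estimation

The two-point estimator
`ADC = ln(S₁/S₂)/(b₂−b₁)` assumes monoexponential signal decay between the
two b-values. Exactly two b-values are used — no multi-b nonlinear fit —
because a non-zero low b-value (default 120 s/mm², against 1200 s/mm²)
already suppresses the perfusion-sensitive fast compartment, and a
two-point subsample keeps the estimator unbiased under that model. On
noiseless monoexponential input the estimator recovers the planted
diffusivity to machine precision (this is tested).

Voxels with non-positive signal are outside the domain of the logarithm;
they are set to the invalid marker and counted, never silently dropped.
Negative ADC estimates (noise pushing S₂ above S₁) are **retained and
flagged** rather than clipped: clipping would truncate the noise
distribution on one side and bias the voxel-difference statistics that the
PRM threshold calibration and classification rest on.

### Hounsfield calibration

The HU scale is *defined* as the linear map with water at 0 and air at
−1000, so calibration fits exactly that affine map through the two ROI
means. Means, not medians, are used because the definition is linear in
expectation; robustness to ROI outliers should come from drawing the ROI
inside homogeneous phantom material, not from changing the estimator.
Calibration is exactly idempotent: applying it to an already-calibrated
volume with its own 0/−1000 references is the identity (tested to 1e-12).

### Registration

Follow-up volumes are always resampled onto the **baseline grid**; the
baseline is the fixed image and classification happens at baseline-voxel
resolution. The acquired-versus-resampled question is thereby resolved in
favor of a single fixed coordinate convention.

*Rigid (CT).* Mutual information is estimated from a 32×32-bin joint
histogram, with intensities linearly binned between each image's 1st and
99th percentiles (robust to a few extreme voxels; the bin count is a
parameter). Optimization is a derivative-free Nelder–Mead simplex over the
6 parameters, preceded by a capture stage that alternates a coarse ±8 mm
translation sweep, a translation-only simplex from a fixed set of
multi-start perturbations, and a coarse ±8° rotation sweep. The capture
stage exists because a joint 6-DOF search started at the identity can be
trapped by local optima when either block is ~10 mm / ~10° from identity;
the sweeps step over those basins at a cost of a few dozen extra objective
evaluations. The seed fixes only the order in which multi-starts are
visited, making results reproducible. The returned transform is guaranteed
not to score below the identity (the identity is kept if the search ever
ends worse), and non-convergence raises an error that carries the
best-found transform and its MI.

*Deformable (MRI).* The thin-plate-spline warp is the exact interpolating
spline in 3D (radial kernel `U(r) = r`, full affine part): it maps each
source landmark onto its target exactly rather than smoothing, matching
the role of hand-placed anatomical correspondences. Landmark
correspondences are **inputs** (CSV of paired world coordinates); automatic
correspondence finding is out of scope. With all targets equal to sources
the fitted warp is the identity; with a constant offset it is a pure
translation (both tested).

*Resampling.* Trilinear interpolation for images, with fractional offsets
below 1e-9 snapped to the lattice so that integer-voxel shifts reproduce
values bit-exactly; voxels whose pull-back leaves the follow-up field of
view get the invalid marker and are excluded through the overlap mask.

### Threshold calibration and classification

The no-change interval is the 95% confidence interval of voxel differences
between two same-day scans, during which no biological change can have
occurred. The default estimator is `1.96 × SD` of the differences
(symmetric, matching the ± form of the shipped clinical thresholds); an
empirical 2.5/97.5-percentile band is available for skewed noise.
Calibration refuses to run on fewer than 30 valid voxels. If the test and
retest volumes are identical the half-width is 0 and a degeneracy warning
is raised.

Classification labels Δ = post − pre as +1 when `Δ > h`, −1 when
`Δ < −h`, else 0. Ties (|Δ| exactly h) are **unchanged**: the null
hypothesis is "no change", so the boundary belongs to the null. Fractions
are percentages of valid VOI∩overlap voxels; invalid voxels are excluded
from numerator and denominator alike and reported as `n_excluded`.
Absolute changed volumes in cm³ are emitted alongside, since longitudinal
plots of changed volume require them.

Shipped fixed thresholds: ADC 0.32 (preclinical) / 0.55 (clinical)
×10⁻³ mm²/s; HU 391 (preclinical) / 100 (clinical). The ADC values are
stored in units of 10⁻³ mm²/s throughout. Thresholds are cohort-wide, not
per lesion. Time courses can use either the pre-treatment scan or an
implantation-day scan as the common baseline; the choice is made when the
registered pairs are built and recorded in the run log.

### PSA response calls

CR (confirmed PSA < 0.2 ng/ml), PR (confirmed ≥ 50% decrease from
baseline), PD (25% increase over the *lower* of baseline and the nadir
observed so far **and** an absolute increase of ≥ 5 ng/ml over that
reference, confirmed), SD as the residual class. Confirmation means a
later measurement at ≥ 4 weeks that itself satisfies the criterion; for
PD the strict reading (confirming value must satisfy both criteria) is the
default and is configurable. When several rules confirm, the earliest
confirmation wins — so appending data after a confirmed call can never
change it — with ties resolved CR > PR > PD.

## The synthetic-data generator

Phantoms are piecewise-constant compartment models with additive Gaussian
voxel noise: a soft-tissue background with an ellipsoidal tumor for ADC
(background 1.0, tumor 0.7 ×10⁻³ mm²/s — inside the physiological
0.5–2.0 range, with treatment response modeled as an upward shift), and a
tibia-like cylinder (cortical shell 1500 HU, trabecular core 300 HU,
lesion 700 HU, air −1000 HU) for CT. Default noise SDs are 0.05–0.15
×10⁻³ mm²/s (ADC) and 30 HU (CT). Follow-ups shift a known subset of
lesion voxels by a chosen effect size (up for response/osteoblastic modes,
down for osteolysis, mixed available), with fresh independent noise and
the ground-truth changed-voxel mask returned. Test–retest pairs are two
independent noise draws over the same structure, so their voxel
differences are Gaussian with SD √2 times the voxel noise — which is
exactly what `calibrate_threshold()` should recover as `1.96·√2·σ`.

Gaussian rather than Rician noise is used on derived maps: PRM statistics
operate on ADC/HU maps whose variability the calibration characterizes by
a symmetric confidence interval, and at map level the Gaussian is the
appropriate model. A Rician DW-signal simulator (`simulate_dw_pair()`) is
provided separately to exercise the ADC estimator on magnitude data.

Registration phantoms add a deterministic smooth texture (a fixed
asymmetric arrangement of six Gaussian bumps, ±amplitude, σ = 6 mm). A
single near-spherical lesion leaves rotation almost unconstrained, and a
periodic (sinusoidal) texture is unusable with a mutual-information
objective: MI is invariant under any intensity bijection, so a half-period
shift — which flips the sinusoid's sign — scores as well as the truth. The
non-periodic bump field has a unique optimum.

Cohorts draw each subject's planted changed fraction from its group's
truncated normal: responder mean 0.172, progressor mean 0.071 (the
clinical stable-versus-progressive group means this package's validation
targets), with between-subject SDs 0.04 and 0.02 — small spreads chosen
once so that group separation reflects the construction, not a tuned
overlap.

**What passing tests do and do not show.** The phantoms have sharp
compartment borders, stationary Gaussian noise, no acquisition artifacts,
no partial-volume gradients, no anatomy-dependent deformation, and
registration truth is available by construction. Passing the suite
demonstrates that the estimators, the calibration identity, the optimizer
and the classification bookkeeping are correct — not that clinical scans
with motion, susceptibility distortion or Rician map noise will behave as
cleanly.

## Numerical choices

- Grids count as shared when dimensions match and spacing/origin/
  orientation agree within 1e-4 relative tolerance (float32 NIfTI headers
  cannot round-trip doubles).
- Invalid voxels are IEEE NaN; every consumer tests `is.na()` and reports
  exclusion counts. Label NIfTIs code invalid as −128 in int8.
- The TPS linear system gets one step of iterative refinement after the
  direct solve, and warp evaluation computes landmark distances by
  explicit coordinate subtraction; both are needed to hold the 1e-8 mm
  landmark-interpolation guarantee (the expanded quadratic-form distance
  cancels catastrophically near landmarks).
- Rigid parameters are optimized in scaled units (10° / 10 mm per unit) so
  the default simplex step sizes are commensurate across rotation and
  translation.
- Test problem sizes: 10⁵-voxel volumes for calibration and null-coverage
  checks, ~36×36×28 phantoms for registration recovery, 10³-voxel
  instances for the brute-force classification oracle — sizes at which the
  Monte-Carlo tolerances quoted in the tests (±1% coverage, ±2%
  calibration) are comfortably above sampling noise.

## Known limitations

- No automatic deformable correspondence: TPS needs user landmarks.
- Rigid capture range is the sweep range (~±12 mm, ±12°); grosser
  misalignment needs a manual initialization.
- Masks are inputs; no segmentation is provided.
- No joint ADC×HU multivariate classification; modalities are analyzed
  separately.
- DICOM is not parsed; convert series to NIfTI-1 upstream (e.g. with
  `dcm2niix`).
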