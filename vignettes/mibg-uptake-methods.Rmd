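---
title: "Quantifying myocardial MIBG uptake in three dimensions: models, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myocardial MIBG uptake in three dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibguptake)
```

## The problem

Cardiac sympathetic innervation imaging with iodine-123
metaiodobenzylguanidine (MIBG) separates Lewy body disease (LBD —
Parkinson's disease and dementia with Lewy bodies) from clinically similar
non-LBD conditions: denervated LBD hearts take up markedly less tracer. The
conventional metric, the planar heart-to-mediastinum count ratio (H/M),
normalizes heart counts by a low-count mediastinal background and has
limited accuracy, with the two diagnostic groups overlapping.

`mibguptake` implements a fully non-invasive *uptake index*: a myocardial
count measure (the *output function*) divided by an estimate of the
administered dose obtained from the first-pass bolus (the *input
function*), with a per-scanner calibration factor linking the two count
scales,

$$\mathrm{index} = s \cdot \frac{C_\mathrm{myo}}{CF \cdot \mathrm{AUC}},$$

where $C_\mathrm{myo}$ is the mean sector count of a myocardial SPECT polar
map (or the mean heart ROI count of a static planar image for the 2D
variant), $\mathrm{AUC}$ is the integral of the gamma-variate fit to the
pulmonary-artery time-activity curve, $CF$ is the 2D–3D count-conversion
factor, and $s$ is a fixed display scale. No arterial sampling and no
attenuation or scatter correction are required.

Because no patient images ship with the package, every stage is validated
on a digital phantom with known ground truth, and the package's standard
"study" is a simulated cohort whose group distributions mirror the
published clinical separation.

## The input function

The dynamic chest acquisition is 120 frames of 1 s on a 128×128 grid
(3.3 mm pixels) following a compact bolus. The pulmonary-artery focus is
detected automatically: pixels whose peak amplitude exceeds 5× their
pre-bolus baseline (with a one-count floor, so empty baselines do not pass
trivially) are gathered inside an upper-central chest window; the cluster
with the earliest time-to-peak wins (within 2 frames of the minimum — the
artery peaks before the lungs, myocardium and soft tissue), and the ROI
center is its amplitude-weighted centroid. The ROI is a fixed 3-pixel
diameter circle; its time-activity curve (TAC) is the *sum* of the 9 pixels
whose centers lie within 1.5 px of the ROI center. A mean would merely
rescale the AUC and cancel in the index; the sum is fixed so counts are
bit-reproducible.

The first pass is modeled as a gamma variate
$g(t) = K\,(t-t_0)^{\alpha} e^{-(t-t_0)/\beta}$. The fit window runs from
the last pre-peak sample below 10% of the peak to the first post-peak
sample below 30% of the peak or the first post-peak rise (recirculation),
whichever comes first — standard gamma-variate practice. Starting values
come from the log-linearization
$\ln C = \ln K + \alpha \ln(t-t_0) - (t-t_0)/\beta$ over a grid of
candidate $t_0$ (every 0.5 s from 0 to the peak time); the best seed is
refined by Levenberg–Marquardt least squares with positivity bounds. The
input function is the closed-form integral

$$\mathrm{AUC} = K\,\beta^{\alpha+1}\,\Gamma(\alpha+1),$$

so frame discretization does not bias it. The tests verify this closed
form against adaptive quadrature (1e-6 relative over 100 random parameter
sets), exact parameter recovery on noiseless model data (≤1e-3 relative),
scale and time-shift equivariance, and a median AUC error ≤5% under
Poisson noise at a peak of 500 counts.

## The planar chain

The 5-min static image (256×256) yields two conventional metrics. The
heart ROI is found as the intensity-weighted centroid of the smoothed
uptake blob in the cardiac window of the chest; if its mean count fails a
1.5× body-background contrast gate — the low-uptake situation typical of
LBD — a fixed-size template ROI is placed at the default anatomical
position and the result is flagged *virtual*, mirroring clinical practice
of "virtually assuming" a myocardium on low-uptake studies. The
mediastinal ROI is a fixed upper-midline rectangle spanning 10% of the
image height; published ROI dimensions are not available, so both
geometries are configurable. H/M is the ratio of ROI mean counts; the
planar uptake index is the heart ROI mean divided by the AUC, scaled.

## The SPECT chain

Projections (60 views over 360°, 64×64, 20 s/view) are reconstructed by
ordered-subsets expectation maximization with 4 subsets and 30 iterations,
no scatter or attenuation correction and no resolution recovery, matching
the acquisition protocol the method targets. The projector/backprojector
pair is a rotation-based parallel-beam operator with bilinear in-plane
interpolation, assembled once per geometry as a sparse matrix; OSEM uses
interleaved subsets (view $v$ in subset $v \bmod 4$), uniform positive
initialization, an $\varepsilon = 10^{-12}$ zero-sensitivity guard, and is
nonnegative by construction. On noiseless consistent data the
reconstruction reprojects to the measured data within 1% and the data
likelihood is non-decreasing — both tested.

The left-ventricular long axis is estimated as the intensity-weighted
principal axis of voxels above 50% of the maximum; the volume is resampled
(trilinear, isotropic at the original voxel size) so slices are
perpendicular to the axis. An isotropic or empty mask (no determinate
axis) falls back to a template geometry and sets the virtual flag. The
apex-to-base slice range keeps slices whose in-plane mask area reaches at
least 10% of the largest slice: the one-voxel caps of an ellipsoidal shell
are not rings, and including them would inflate the polar map's apparent
nonuniformity severalfold.

The polar (bull's-eye) map uses 10 rings × 36 sectors — our choice; only
the per-sector rule is prescribed by the method lineage: counts are
sampled along each radial ray at 1-voxel steps and the sector value is the
maximum over radius of the running mean of three consecutive samples
(`sector_max3()`; the profile `c(0, 10, 20, 10, 0)` gives 40/3). The
output function defaults to the polar-map *mean* (the quantity correlated
against planar counts in the clinical validation), with the total exposed
as an option since the method's description uses both terms.

The conversion factor $CF$ is the least-squares slope, through the origin,
of polar-map means on planar heart means over a calibration set —
proportionality is the model's premise, and the slope direction is fixed
by requiring dose invariance of the index. By default the package
calibrates on 8 dedicated noiseless phantoms spanning concentrations
0.4–2.8 rather than on the analysis subjects, to avoid leakage in
simulation studies; `calibration = "pooled"` reproduces the pooled
single-cohort behaviour.

## The digital phantom

The generator emulates the three acquisition channels of one subject from
a single injected-dose scale and myocardial concentration, so indices
computed from different channels are mutually consistent:

* **Dynamic**: organs are 2D ellipses in normalized image coordinates.
  The pulmonary-artery disk carries the pure bolus curve — gamma variate
  (defaults $K = 13$ counts/pixel/frame at unit dose, $\alpha = 3$,
  $\beta = 1.5$ s, $t_0 = 8$ s) plus a delayed recirculation copy
  (fraction 0.3, delay 12 s, the simplest shape giving a first peak
  followed by recirculation). Lungs, myocardium, liver and soft tissue add
  slower uptake curves on a zero pre-bolus baseline. The bolus shape
  parameters are stated defaults, not values inferred from data: the
  clinical protocol does not publish them.
* **Planar**: additive organ contributions over a soft-tissue background
  (a projection adds), so a noiseless heart/mediastinum ratio is
  `1 + concentration` by construction.
* **SPECT**: an ellipsoidal myocardial shell (long axis along z,
  tiltable), optional angular defects scaling shell voxels by
  `(1 - depth)`, a faint absolute body background, and the same
  parallel-beam projector used by OSEM, followed by optional Poisson
  noise.

Per-group true concentrations follow a log-normal matched to the target
median and IQR (`mu = log(median)`,
`sigma = log(q3/q1) / (2 qnorm(0.75))`); the defaults are the published
group medians and IQRs (LBD 0.63, IQR 0.52–0.82; non-LBD 1.70, IQR
1.53–2.03) and the default cohort is 37 LBD / 40 non-LBD subjects.

What the phantom does *not* emulate — and what passing tests therefore do
not establish about patient data: anthropomorphic anatomy, photon
attenuation and scatter, depth-dependent collimator blur, cardiac and
respiratory motion, and inter-subject anatomical variability. The phantom
validates the *computational* chain (detection, fitting, reconstruction,
mapping, calibration, statistics), not the physics of acquisition.

## Numerical and design choices

* Index display scale: 10 (a pure convention; it cancels in every ROC and
  group comparison). With this phantom's count levels (heart means around
  300 counts/pixel, AUCs around 3000 counts·s) it places indices in the
  0.4–2.8 range where the clinical indices live, which keeps simulated and
  published numbers visually comparable.
* Gamma-fit failure policy: subjects whose TAC has no detectable peak or
  whose fit does not converge are excluded from diagnostics and listed in
  the report.
* Quartiles use the linear-interpolation convention; the median's 95% CI
  uses binomial order statistics; sample variance uses the n−1
  denominator — all fixed so summaries are bit-reproducible.
* Exact Mann–Whitney (U = min(U1, U2), full enumeration with mid-ranks at
  combined n ≤ 20, two-sided p = min(1, 2·min(tail probabilities)),
  tie-corrected normal approximation above) and two-sided Fisher
  (sum-of-smaller-probabilities) follow the conventions that reproduce the
  published contingency-table p-value.
* ROC analysis is empirical, with disease-positive defined as *low* index
  (matching the "<" decision criteria of this clinical literature), AUC by
  the Mann–Whitney identity with ties counted one half, and the decision
  threshold chosen by the Youden index with a midpoint tie-break. Binormal
  quasi-maximum-likelihood ROC fitting and the multi-reader
  Dorfman–Berbaum–Metz AUC comparison are intentionally not reproduced;
  a paired structural-components (DeLong-style) test compares AUCs
  instead.
* Degenerate inputs raise classed conditions (`NoBolusDetected`,
  `FitFailed`, `RoiOutOfBounds`, `ZeroMediastinum`, `ZeroAuc`,
  `IndivisibleSubsets`, `AxisUndetermined`, `EmptySlice`, `TooFewPairs`,
  `OneClassOnly`, ...) so callers can branch on failure modes.

## A worked example

```{r example, eval = FALSE}
cfg <- phantom_config(noise = FALSE)
subject <- make_subject_phantom(cfg, "demo", "non-LBD",
                                concentration = 1.7, seed = 42)

roi <- detect_pa_roi(subject$dynamic)
fit <- fit_gamma_variate(extract_tac(subject$dynamic, roi))
auc <- gamma_auc(fit)

rois <- place_heart_roi(subject$planar)
hm_ratio(subject$planar, rois)
planar_uptake_index(subject$planar, rois, auc)$index

recon <- osem_reconstruct(subject$projections)
pm <- build_polar_map(reorient_short_axis(recon))
cal <- calibrate_on_phantoms(cfg)
spect_uptake_index(pm, cal, auc)$index
```

And the full simulated study:

```{r cohort, eval = FALSE}
study <- run_cohort(n_lbd = 37, n_nonlbd = 40, seed = 2024)
study$report
```

## Problem sizes used in validation

The shipped tests and the acceptance script run the chain at the protocol's
native sizes — 120×128×128 dynamic series, 256×256 planar images, 64³
volumes with 60-view projections and the full 4-subset/30-iteration OSEM —
and the full 77-subject simulated cohort; only auxiliary property checks
(e.g. likelihood monotonicity) use reduced grids, chosen to exercise the
same code paths at a few seconds per check.

## Known limitations

* The projector is ideal parallel-beam: no attenuation, scatter or
  depth-dependent response, so reconstruction accuracy statements are
  about the algorithm, not about quantitative SPECT in tissue.
* The published clinical study reports no fitted bolus parameters or AUC
  values, so the input function can only be validated by construction and
  by internal consistency, never against printed patient numbers.
* The heart/mediastinum ROI geometries reproduce the *logic* of the
  published automatic methods, not their exact published implementations,
  whose internals are unavailable.
* The virtual-ROI fallback makes low-uptake planar quantification depend
  on the template position being anatomically sensible; grossly abnormal
  anatomy would need a user-supplied template.
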