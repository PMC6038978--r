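# mibguptake

Non-invasive, three-dimensional quantification of myocardial
¹²³I-metaiodobenzylguanidine (MIBG) uptake for the differential diagnosis
of Lewy body disease (LBD: Parkinson's disease and dementia with Lewy
bodies).

Cardiac MIBG imaging exploits the sympathetic denervation of LBD hearts,
which take up far less tracer than non-LBD hearts. The conventional planar
heart-to-mediastinum count ratio (H/M) has limited accuracy; this package
implements a calibrated *uptake index* whose numerator comes from the
myocardial SPECT polar map and whose denominator is a dose estimate
derived entirely from the images:

```
index = s · Cmyo / (CF · AUC)
```

* `AUC` — the **input function**: the integral `K·β^(α+1)·Γ(α+1)` of a
  gamma-variate fit `g(t) = K (t − t0)^α e^(−(t−t0)/β)` to the
  pulmonary-artery first-pass time-activity curve on dynamic chest images
  (automatic 3-pixel ROI detection included).
* `Cmyo` — the **output function**: the mean sector value of a 10-ring ×
  36-sector polar (bull's-eye) map built from an OSEM-reconstructed
  (4 subsets, 30 iterations), short-axis-reoriented SPECT volume; each
  sector is the maximum 3-sample running mean along its radial profile.
  The 2D variant uses the mean heart-ROI count of the static planar image.
* `CF` — the 2D–3D count-conversion factor, the through-origin regression
  slope of polar-map counts on planar heart counts over a calibration set.
* `s` — a fixed display scale (default 10).

Because both `Cmyo` and `AUC` scale with the administered dose, the index
is dose-invariant and proportional to true myocardial concentration —
properties the test suite verifies end to end.

The package also ships:

* a **digital phantom** generating the full acquisition set of a subject
  (dynamic 120×128×128 series with bolus + recirculation kinetics, static
  256×256 planar image, 64³ activity volume, 60-view parallel-beam
  projections, Poisson noise) with known ground truth;
* a **diagnostics layer**: empirical ROC with Youden-index criterion
  selection, sensitivity/specificity/PPV/NPV/accuracy, group summaries
  with median CIs, overlap intervals, exact Mann-Whitney and Fisher
  tests, Spearman correlation, and a paired DeLong-style AUC comparison;
* a **cohort pipeline** (`run_cohort()`) simulating the standard 37 LBD /
  40 non-LBD study and producing a full diagnostic-accuracy report;
* a thin CLI (`inst/cli/mibguptake`) with `simulate`, `input-fn`,
  `quantify-spect`, `calibrate` and `report` subcommands.

## Worked example

A noiseless phantom subject with true myocardial concentration 1.7
(a typical non-LBD level):

```r
library(mibguptake)

cfg <- phantom_config(noise = FALSE)
subject <- make_subject_phantom(cfg, "demo", "non-LBD",
                                concentration = 1.7, seed = 42)

## input function from the dynamic series
roi <- detect_pa_roi(subject$dynamic)          # 3-px ROI on the PA focus
fit <- fit_gamma_variate(extract_tac(subject$dynamic, roi))
c(fit$K, fit$alpha, fit$beta, fit$t0)
#> [1] 104.0   3.0   1.5   8.0        # alpha/beta/t0 recovered exactly
auc <- gamma_auc(fit)                          # 3159 counts·s

## planar chain
rois <- place_heart_roi(subject$planar)
hm_ratio(subject$planar, rois)                 # 2.77
planar_uptake_index(subject$planar, rois, auc)$index   # 1.32

## SPECT chain
recon <- osem_reconstruct(subject$projections) # OSEM 4 subsets x 30 iter
pm <- build_polar_map(reorient_short_axis(recon))
cal <- calibrate_on_phantoms(cfg)              # CF = 0.127, r > 0.9999
spect_uptake_index(pm, cal, auc)$index         # 1.28
```

The two uptake indices agree (1.32 planar vs 1.28 SPECT) because both
divide consistent myocardial count measures by the same input function —
the design premise of the method. An LBD-level concentration (0.63) yields
indices around 0.5–0.7, and the simulated cohort separates the groups:

```r
study <- run_cohort(n_lbd = 37, n_nonlbd = 40, seed = 2024)
study$report
#> Diagnostic accuracy (positive call: index below criterion)
#> method     AUC criterion sensitivity specificity   PPV   NPV accuracy
#> hm       1.000     2.102        1.00        1.00  1.00  1.00     1.00
#> planar   0.994     1.091        1.00        0.95  0.95  1.00     0.97
#> spect    0.999     0.819        1.00        0.97  0.98  1.00     0.99
```

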