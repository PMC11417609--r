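# bonexcal

Cross-calibration of bone microarchitecture measurements between
first-generation (XCTI, 82 µm voxels) and second-generation (XCTII, 61 µm
voxels) HR-pQCT scanners.

When a research site replaces its first-generation scanner, ongoing
longitudinal studies suddenly mix two instruments whose outputs are not
interchangeable: the finer voxels of the second generation see thinner
trabeculae and smaller cortical pores, and its analysis protocol measures
microstructure directly from the binary image rather than deriving it from
density. `bonexcal` provides, as reusable and tested R functions, the full
analysis chain needed to quantify and bridge that gap:

* **Synthetic ground truth** — analytic bone phantoms (plate and rod
  lattices, correlated Gaussian fields, porous cortical shells) whose
  morphometry is known by construction, plus a paired-scan simulator that
  images one structure at both resolutions (Gaussian PSF, box-average
  resampling, additive density noise) and a measurement-level cohort
  simulator with configurable inter-scanner slope, intercept and noise.
* **Segmentation** — the two binarization protocols whose disagreement
  drives the method differences: a Gaussian filter with fixed BMD thresholds
  (the standard second-generation approach), and a Laplace–Hamming (LH)
  frequency-domain filter with a fixed global threshold (the
  first-generation-style approach).
* **Direct morphometry** — distance-transform measures over binary volumes:
  model-independent local thickness (largest inscribed sphere), trabecular
  separation, medial-axis spacing (Tb.N, Tb.1/N.SD), cortical porosity and
  pore diameter, plus the density/geometry outcomes (Tt.BMD, Tb.BMD, Ct.BMD,
  Tb.Ar, Ct.Ar, Ct.Pm) and the indirect density-derived pathway. Fourteen
  outcomes in all.
* **Cross-calibration** — for each outcome, the hybrid cross-validation /
  bootstrap procedure: split the cohort (by default 24 training / 12 test
  subjects), draw 1000 bootstrap sets of 12 training pairs with replacement,
  fit ordinary least squares `XCTII = slope · XCTI + intercept` per draw,
  and report the averaged slope, intercept and R². Applying the equation to
  held-out XCTI values gives estimated second-generation outcomes, `XCTII*`.
* **Validation statistics** — mean absolute percent error of `XCTII*`
  against measured XCTII with t-based 95% CIs, Bland–Altman limits of
  agreement with proportional-bias testing, correlation-strength
  classification (strong R² > 0.9 / moderate 0.7–0.9 / weak < 0.7), and
  paired-t comparison of the two segmentation protocols' errors.

The distance-transform primitives (Euclidean distance transform, local
thickness, distance ridge) are implemented in C++ via Rcpp.

## Worked example

Calibrate trabecular bone volume fraction between scanners on a simulated
36-subject paired cohort (inter-scanner slope 1.66, intercept 0.01, noise set
for a population R² of 0.97):

```r
library(bonexcal)

pars <- data.frame(parameter = "BV/TV", true_slope = 1.66, true_intercept = 0.01,
                   xcti_mean = 0.15, xcti_sd = 0.04,
                   noise_sd = noise_sd_for_r2(1.66, 0.04, 0.97))
cohort <- generate_paired_cohort(cohort_sim_spec(36, pars, seed = 42))

plan <- split_cohort(cohort$xcti, n_test = 12, seed = 1)
eq <- bootstrap_calibrate(cohort, "BV/TV", n_boot = 1000, draw_size = 12,
                          seed = 7, training_ids = plan$training_ids)
eq
#> calibration_equation BV/TV: XCTII* = 1.6526 * XCTI + 0.0119 (R2 = 0.976)
#>   1000 bootstrap draws of 12 from 24 training pairs (0 redrawn, 0 dropped)
classify_correlation(eq$r_squared)
#> [1] "strong"

xt <- subset(cohort$xcti,  subject_id %in% plan$test_ids)
yt <- subset(cohort$xctii, subject_id %in% plan$test_ids)
est <- apply_calibration(eq, xt$value)
percent_error(est, yt$value)
#> mean absolute percent error 3.84% (95% CI 1.00, 6.68), n = 12
bland_altman(est$estimates, yt$value)
#> Bland-Altman: mean difference 0.0029, 95% LoA [-0.0219, 0.0277], n = 12
#>   proportional bias slope 0.0444 (p = 0.373)
```

The recovered equation sits on the simulated truth (1.66, 0.01), the held-out
estimation error is a few percent, and the Bland–Altman limits bracket zero
with no significant proportional bias — the behaviour expected when the
inter-scanner relationship really is linear.

The imaging arm works the same way from a phantom:

```r
ph <- generate_phantom(phantom_spec("plate_lattice", extent_mm = c(2, 1, 1),
                                    thickness_um = 200, spacing_um = 1000), 20)
scan <- simulate_scan(ph$truth, 1200, scanner_profile("XCTII_like"), seed = 3)
mask <- binary_volume(resample_mask(ph$masks$trabecular$voxels, 20, 61), 61)
bone <- laplace_hamming_binarize(scan, mask)
c(bvtv = bvtv(bone, mask), tb_th = direct_tb_th(bone, mask))
```

`run_pipeline(demo_config_path(), "out")` drives every stage — phantoms,
paired scans, both segmentations, morphometry, cohort, calibration,
validation — from one YAML configuration and writes CSV/JSON artifacts plus a
checksummed manifest; reruns are byte-identical.

## Documentation

The methods vignette (`vignettes/cross-calibration-methods.Rmd`) describes
the models, the tunable parameters with their defaults and units, the
numerical conventions (distance-transform boundary handling, thresholding
scales, degenerate-draw policy), and what the synthetic data do and do not
emulate about in vivo scans.
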