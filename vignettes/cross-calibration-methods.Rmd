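---
title: "Cross-calibrating dual-resolution bone microarchitecture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-calibrating dual-resolution bone microarchitecture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonexcal)
```

# The problem

High-resolution peripheral quantitative CT (HR-pQCT) quantifies trabecular
and cortical bone microarchitecture in vivo at the distal radius and tibia.
The two scanner generations differ in ways that matter for every outcome:
the first generation acquires 82 µm isotropic voxels and derives much of its
trabecular morphometry indirectly from density under a plate model, while
the second generation acquires 61 µm voxels and measures everything directly
from the segmented binary image with distance-transform methods. A
trabecula of 100–150 µm spans one to two voxels on either system, so
partial-volume blurring, the segmentation filter, and the measurement
pathway each imprint a scanner-specific bias. Longitudinal studies that
span a scanner upgrade therefore need *cross-calibration*: a per-outcome
mapping from first-generation values onto the second-generation scale.

`bonexcal` implements that analysis chain end to end and — because paired
in vivo scans are rarely shareable — ships a synthetic-data module that
generates every input the chain needs, with analytically known ground truth.

# The calibration model

For each outcome (14 are handled: Tt.BMD, Tb.Ar, Tb.BMD, BV/TV, Tb.N,
Tb.Th, Tb.Sp, Tb.1/N.SD, Ct.Ar, Ct.BMD, Ct.Pm, Ct.Po, Ct.Th, Ct.Po.Dm) the
inter-scanner relationship is modelled as linear,

$$\mathrm{XCTII} = a\,\mathrm{XCTI} + b + \varepsilon,$$

and estimated by a hybrid cross-validation / bootstrap procedure:

1. the paired cohort is split at random into a training set (default 24
   subjects) and a held-out test set (default 12);
2. from the training pairs, 1000 bootstrap sets of 12 pairs are drawn with
   replacement; each is fit by ordinary least squares (closed-form normal
   equations);
3. the reported slope, intercept and $R^2$ are the arithmetic means over
   the 1000 per-draw fits;
4. the averaged equation is applied to the test subjects' XCTI values to
   produce estimates XCTII\*, which are validated against the measured
   XCTII values.

Draws in which all XCTI values coincide admit no regression; they are
redrawn (and counted in the returned object) rather than skipped, so
exactly `n_boot` fits enter the average with uniform weight. Subjects
missing either side of a pair are dropped pairwise per outcome and counted.
The draw size of 12 — half the training set rather than a full-size
resample — is unusual for a bootstrap but is kept as the procedure's
defining choice; both `draw_size` and `n_test` are parameters.

Correlation strength is classified as strong ($R^2 > 0.9$), moderate
($0.7 < R^2 < 0.9$) or weak ($R^2 < 0.7$); the intervals are open, and a
value exactly on a boundary goes to the lower class with a warning.

Validation uses the mean absolute percent error
$100\,|\mathrm{XCTII}^* - \mathrm{XCTII}|/\mathrm{XCTII}$ with a t-based
95% confidence interval of the mean (the interval form is our choice — a
plain t interval on the per-subject errors), Bland–Altman mean difference
with 95% limits of agreement $\bar d \pm 1.96\,s_d$, proportional bias as
the OLS slope of differences on means with its two-sided p-value, and a
two-sided *paired* t-test when comparing the per-subject errors of two
analysis protocols. The paired form is a deliberate choice: the two
protocols are applied to the same subjects, so the pairing is real even
though an unpaired test would also be defensible; the assumption is noted
in the reports.

# Synthetic data

## Phantoms

Four structural families with analytic truth:

* **plate_lattice** — parallel plates of thickness $t$ at pitch $s$
  (vectors allowed, giving interleaved pitches). BV/TV $= t/s$,
  Tb.Th $= t$, Tb.Sp $= s - t$, Tb.N $= 1/s$ exactly, by construction.
* **rod_lattice** — a square lattice of rods along one axis:
  Tb.Th $=$ diameter, BV/TV $= \pi r^2 / s^2$.
* **gaussian_field** — a correlated Gaussian random field thresholded at a
  quantile: BV/TV equals the requested solid fraction.
* **cortical_shell** — a hollow cylinder of wall thickness $w$ with
  longitudinal through-pores. When a target pore fraction is requested the
  pore radius is adjusted after rounding the pore count so the analytic
  fraction is hit exactly; Ct.Th $= w$, Ct.Po.Dm $=$ realised pore
  diameter. The generator also emits the periosteal (outer disc) mask.

Truth values derive from the analytic definition only, never from the
raster, so they are identical across grids. Rasterization marks a voxel
solid when its centre is inside the structure, and refuses grids on which
the smallest feature falls below two voxels. Plate lattices are shifted so
that volume faces bisect gaps: the distance transform treats the volume
boundary as a continuation of whatever phase touches it, and with this
alignment boundary half-gaps measure the full gap width (infinite-lattice
semantics) while no plate is ever truncated mid-slab.

## Scanner model

A `scanner_profile` degrades a truth volume in four steps: multiply by the
tissue matrix density (default 1200 mgHA/cm³, the conventional fully
mineralised value); convolve with an isotropic Gaussian PSF; box-average
down to the profile voxel size; add white Gaussian density noise (default
SD 25 mgHA/cm³). Two presets fix the voxel sizes of the two scanner
generations, 82 and 61 µm. The PSF sigma defaults to 0.6 × voxel so blur
scales with resolution — neither vendor publishes a PSF, and these
profiles are qualitative stand-ins intended to reproduce the *direction*
of resolution effects, never device-accurate models.

Blurring is FFT-based and therefore periodic; the lattice phantoms are
periodic-compatible, which is why they pair naturally with it. Resampling
uses exact overlap weighting: each coarse voxel is the exact area average
of the fine signal over the interval it covers, so volume means and total
mineral mass are conserved exactly whenever the extent is commensurate
with the coarse grid (a trailing partial voxel averages just its sliver).

## Cohort simulator

The measurement-level simulator draws, per subject and outcome,
$x \sim N(\mu, \sigma_x^2)$ for the first-generation value and sets
$y = a x + b + e$, $e \sim N(0, \sigma_e^2)$, with the noise on the XCTII
side only — matching the direction in which the calibration is estimated.
`noise_sd_for_r2()` inverts the population relation
$R^2 = a^2\sigma_x^2 / (a^2\sigma_x^2 + \sigma_e^2)$ to target a given
correlation strength.

# Segmentation

## Gaussian + fixed BMD thresholds

A truncated discrete Gaussian (default sigma 0.8 voxels, support 1 voxel)
smooths the calibrated volume; voxels at or above a fixed density
threshold inside the compartment mask are bone. Defaults of 320 mgHA/cm³
(trabecular) and 450 mgHA/cm³ (cortical) follow conventional
second-generation practice; the volume must be density-calibrated or the
operation refuses.

## Laplace–Hamming + fixed global threshold

The LH filter is applied in the frequency domain:

$$H(f) = \bigl[(1-w) + w \, L(f)\bigr]\, W(\rho), \qquad
L(f) = \sum_i 4\sin^2(\pi f_i),$$

where $L$ is the exact magnitude response of the (negated) discrete
6-neighbour Laplacian, $\rho$ is radial frequency as a fraction of the
maximal representable frequency, and $W$ is a Hamming window
$0.54 + 0.46\cos(\pi\rho/\rho_c)$ vanishing at the cutoff $\rho_c$. The
Laplacian term boosts thin plates (ridges) and deepens small pores (dips)
relative to the low-frequency baseline; the window bounds noise
amplification. Because the Laplacian destroys the density scale, the
global threshold is defined on the *filtered* intensity scale, as a
fraction (default 0.4) of the in-mask positive maximum. Volumes are
mirror-padded to even sizes before the FFT and cropped back.

Defaults: cutoff 0.8, Laplacian blend weight 0.5, threshold fraction 0.4.
The cutoff deserves a note: a much lower cutoff (e.g. 0.4 of the radial
maximum) removes precisely the one-to-two-voxel spatial frequencies that
carry thin trabeculae and small pores, reducing the filter to a soft
low-pass and erasing the fine-feature sensitivity that distinguishes this
protocol from the Gaussian one. With the defaults, on a phantom with 150 µm
plates and ~74 µm pores imaged at 61 µm, the LH protocol retains the thin
plates near their true thickness and detects the sub-voxel pores, while
the Gaussian protocol widens the plates (BV/TV 0.24 vs truth 0.15) and
finds no pores at all; on features tens of voxels across the two protocols
agree within ~1% of voxels. A constant (or non-positive after filtering)
input yields an empty segmentation with a warning. All three constants are
exposed in the configuration.

# Morphometry

## Local thickness

Local thickness follows the model-independent inscribed-sphere definition:
the value at a voxel is the diameter of the largest sphere that contains
the voxel and fits inside the phase. Two discrete conventions matter:

* **Sphere centres** live on the half-voxel grid (voxel centres, face and
  edge midpoints, corners). Centre-only conventions underestimate
  structures an even number of voxels wide by a full voxel — fatal when a
  thin plate spans two voxels; with half-grid centres an $n$-voxel slab
  measures $n$ for even and odd $n$ alike.
* **Radii** are measured to the phase boundary: distance to the nearest
  background voxel centre minus half a voxel.

The implementation computes the exact Euclidean distance transform
(Felzenszwalb–Huttenlocher, separable) on the supersampled grid, prunes
centres whose sphere is contained in a neighbouring centre's sphere, and
paints the survivors in decreasing radius order. It matches a brute-force
enumeration oracle to numerical precision on every tested fixture.
Residual discretisation effects are below about half a voxel (off-axis
centres can slightly inflate a slab; jagged cylinder boundaries deflate a
narrow pore), which is why the pore-diameter fixtures are rasterised at
10 µm. Distances are computed only to background *inside* the volume; the
boundary continues the phase, so slabs and lattices spanning the field of
view behave as infinite.

## Outcome definitions

* **BV/TV** — bone voxels / mask voxels.
* **Tb.Th, Ct.Th** — mean local thickness of the bone phase (mm).
* **Tb.Sp** — mean local thickness of the marrow phase (mask minus bone).
* **Tb.N, Tb.1/N.SD** — the medial axes of the trabeculae are the distance
  ridge of the bone phase (voxels whose maximal sphere is contained in no
  neighbour's). The local thickness of everything between the axes, plus
  the one-voxel axis width, is the centre-to-centre spacing distribution;
  Tb.N is the inverse of its mean and Tb.1/N.SD its standard deviation.
  Fewer than two 26-connected ridge components is an error.
* **Ct.Po, Ct.Po.Dm** — pore fraction of the cortical mask, and mean local
  thickness of the pore phase; with no pores, Ct.Po is 0 and Ct.Po.Dm is
  reported missing rather than zero.
* **Indirect pathway** (first-generation style) — BV/TV = Tb.BMD / matrix
  density (default 1200 mgHA/cm³, configurable), Tb.Th = BV/TV / Tb.N,
  Tb.Sp = (1 − BV/TV) / Tb.N, with Tb.N always measured directly. The
  pipeline applies this pathway on the XCTI-like arm by default
  (configurable), since which first-generation outcomes are direct versus
  derived is protocol-dependent.
* **Densities** — means of the calibrated values over the total,
  trabecular and cortical masks (mgHA/cm³).
* **Areas** — mean per-slice cross-sections (mm²). **Ct.Pm** — mean
  per-slice marching-squares contour length of the periosteal mask;
  voxel-edge perimeters were rejected as upward-biased, though marching
  squares itself still overestimates smooth curved contours by a few
  percent at coarse voxels (it is exact on axis-aligned rectangles).

Internal lengths are millimetres and densities mgHA/cm³ throughout.

# Numerical choices and degenerate inputs

* OLS is closed-form; $R^2 = 1$ is reported for an exact fit even when the
  response variance is zero in a degenerate draw.
* Bootstrap redraws (degenerate draws), dropped pairs, and excluded
  zero-denominator subjects in percent errors are all counted and surfaced
  in objects, warnings and the pipeline manifest — no silent drops.
* Bland–Altman proportional bias is undefined for constant means and
  flagged `NA` with a warning; zero-variance paired differences take the
  limit p-values (1 if the means agree, 0 otherwise).
* All simulation functions take explicit integer seeds; the same seed
  reproduces outputs bit-exactly and the pipeline manifest records the
  hash of every artifact. The demonstration configuration reruns
  byte-identically.

# What the synthetic data do and do not show

The phantoms share one ground-truth structure across both scanner
profiles, which is the point of a paired design, and they reproduce the
mechanisms that drive inter-scanner disagreement: partial-volume
thickening of thin plates at coarser voxels, loss of sub-voxel pores, and
filter-dependent retention of fine features. They do **not** emulate
anatomy, beam hardening, ring or motion artifacts, contouring variability,
or the stack-length difference between scan protocols; scanner noise and
PSF values are plausible placeholders, not measurements. Passing tests
therefore demonstrate that the *pipeline* is correct and that the
direction and rough magnitude of resolution and method effects emerge from
first principles — not that any particular in vivo regression coefficient
will be reproduced.

Test problem sizes are chosen to keep the full suite fast while leaving
the conclusions stable: phantoms of a few millimetres rasterised at
10–20 µm, cohorts of 36 subjects, 100–1000 bootstrap draws, and Monte-Carlo
checks of 100 cohorts (slope recovery), 10⁴ pairs (limits-of-agreement
coverage) and 2000 replicates (test size). Larger runs change none of the
qualitative results.

# Known limitations

* Local thickness inherits half-voxel discretisation effects; narrow
  structures should be rasterised or acquired at several voxels per
  feature before quantitative comparison.
* Ct.Pm is biased upward by a few percent on smooth curved contours.
* The LH filter constants are package defaults chosen for mechanism
  fidelity on synthetic structures, not a reconstruction of any vendor's
  proprietary coefficients.
* The cohort simulator is homoscedastic and linear by construction; it
  cannot, by itself, falsify the linearity assumption of the calibration.
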