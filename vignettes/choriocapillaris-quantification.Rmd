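---
title: "Quantifying choriocapillaris flow deficits: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choriocapillaris flow deficits: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choriomap)
```

## The measurement problem

The choriocapillaris is the capillary monolayer that feeds the retinal
pigment epithelium (RPE) and photoreceptors. On en-face OCT-angiography
(OCTA) slabs it appears as a dense granular flow texture; focal loss of
signal ("flow deficits") accompanies aging and precedes clinically visible
age-related macular degeneration (AMD). choriomap quantifies this texture
with two numbers per eye:

* the **CCFA ratio** — the choriocapillaris flow area as a percentage of
  the analyzed area, computed on a locally binarized slab; lower values
  mean more flow deficit;
* the **CV of the CCFA ratio** — the coefficient of variation of the CCFA
  ratio computed over an 18 x 18 grid of equal tiles; higher values mean
  the deficits are more heterogeneous (patchy) rather than uniform.

An eye is flagged *high risk* of being an AMD fellow eye when
CCFA ratio < 58.5 % **and** CV >= 0.165, with exactly these boundary
semantics (strict on the ratio, inclusive on the CV). Cohort-level
inference then relates that flag to RPE abnormality (graded from fundus
autofluorescence, FAF) and to asymmetrically dilated choroidal large
vasculature, adjusting for age and sex.

## Pipeline stages and their assumptions

### Magnification correction

OCTA pixel sizes are nominal for a reference eye; the true transverse
scale varies with axial length. The package uses the ratio form of the
modified Bennett ocular magnification term, `q = 0.01306 (AL - 1.82)`:

`factor = (AL - 1.82) / (AL_ref - 1.82)`

so the camera constant cancels. The correction rescales `pixel_scale`
only — the raster is never resampled — and the corrected field is then
center-cropped to the analyzed 2.7 x 2.7 mm square
(`crop_to_field()`). Avoiding interpolation keeps binarization free of
resampling artifacts. The reference axial length defaults to 24.46 mm, a
common device assumption, and is configurable because devices differ and
the correct value is device-specific. Crops whose pixel width is
fractional round to the nearest even integer (symmetric centering) and
are trimmed by at most 17 px so the output divides evenly into the 18-tile
grid; the output is therefore within one tile-width of the nominal target
field, and cropping is idempotent.

### Phansalkar binarization

Flow/non-flow segmentation uses the Phansalkar local threshold,

`T = m (1 + p e^{-q m} + k (s/R - 1))`

with `m`, `s` the local mean and population SD over a circular window
(defaults: radius 15 px, `k = 0.25`, `R = 0.5`, `p = 2`, `q = 10`,
matching the widely used ImageJ implementation). The exponential term
boosts the threshold at dark means, which suits low-contrast OCTA slabs
with variable illumination. Borders are handled by mirror reflection
(edge pixel repeated), which avoids spurious flow voids at the image
edge. A pixel is flow iff its intensity strictly exceeds `T`, so an
all-zero image maps to zero flow. Intensities must be normalized by the
bit-depth maximum (255 or 65535), never by the observed maximum, for
stability across images. The windowed statistics are computed by
FFT-based convolution of the mirrored image with a disc kernel; tests
require agreement with a brute-force per-pixel reference to 1e-6.

One behavior worth knowing: for a *homogeneous* region at intensity above
`ln(8)/10 ~ 0.21`, `T < m` and the whole region classifies as flow. The
rule is designed for textured images where every window mixes both
classes; on synthetic block images only a dark background
(mean < ~0.21) is recovered as background.

### CCFA ratio, tile grid, CV

`ccfa_ratio()` is an exact pixel count: `100 * flow / analyzed`. The
18 x 18 grid ("324 small images") is the scale at which heterogeneity is
scored; at the 2.7-mm field each tile is 0.15 x 0.15 mm, a plausible
lobule scale, and the grid order is configurable. The CV uses the sample
SD (n-1 denominator) over the mean; the package records this convention
in the output provenance since either denominator is defensible. The
tile statistic satisfies two exact identities used as tests: the
whole-image ratio equals the equal-weight mean of the 324 tile ratios
(to 1e-9), and ratios are additive over disjoint masks.

Region comparisons: the FAF-normal region is the analyzed area minus the
abnormal mask. For a CV restricted to a region, tiles count only when at
least half the tile lies inside the region (`region_tile_cv()`); the
half-coverage rule is our choice where no convention exists.

Side comparisons split the image into upper, middle, and lower thirds;
the grading label maps upper/lower to the thicker/thinner
choroidal-vasculature side, the middle band carries no side effect, and
each side's CV is computed over that band's own 6 x 18 tile subgrid. An
alternative reading — whole-image tiles intersected with the bands —
would mix band-boundary tiles into both sides; the band-restricted
version keeps the two sides disjoint and is what `side_metrics()`
implements.

## The synthetic generators

No patient images are distributed, so every stage is validated against
synthetic data whose generating values are known.

**Flow maps** (`generate_flow_map()`): each tile draws a target flow
fraction from a logit-normal distribution calibrated so that the drawn
fractions have *exactly* the requested mean and SD
(`logit_normal_calibrate()` solves the two-moment problem by quadrature;
a naive logit draw would bias the mean by ~0.1 percentage points at the
dispersions used here, which is many standard errors at the test's
replication level). Within a tile, a Gaussian random field is thresholded
at the exact sample quantile, so the realized foreground count equals the
drawn target to within one pixel. Consequences used by the tests: with
`tile_sd = 0` every tile is exact; the whole-map fraction is unbiased for
the generating fraction; and the CV of the drawn tile fractions is
exactly `tile_sd / fraction`, which is how the CV recovery targets are
calibrated (e.g. `tile_sd = 0.182 * 0.581` for a generating CV of 0.182
at the AMD-group level).

**Grayscale rendering** (`render_grayscale()`): flow and background
pixels get intensities `N(0.75, 0.08)` and `N(0.35, 0.08)` by default.
`texture_corr_len` sets the correlation length of the *noise field* (a
unit-variance Gaussian random field smoothed to that width and scaled by
each class SD), not a blur of the composed image: blurring the composed
image would average the pixel-interleaved classes and destroy the
contrast that local thresholding needs, whereas the noise-field
formulation preserves class means exactly at any correlation length.
With the default separability `(0.75 - 0.35)/0.08 = 5`, Phansalkar
recovery of the whole-image CCFA ratio is within ~2 percentage points of
ground truth. A configurable separability floor (default 2) warns when a
parameterization cannot be recovered reliably.

**Cohorts** (`generate_cohort()`): group sizes, covariate distributions,
metric means, FAF/asymmetry prevalences, within-eye region and side
offsets, and RPE volumes default to the published cohort's values
(38 AMD fellow eyes vs 22 controls; CCFA 58.1 vs 62.9 %; CV 0.182 vs
0.152; FAF-region offset -5.1 pp; side offsets -1.7 pp and +0.017; RPE
volumes 0.020/0.022 um^3). Printed dispersions are standard errors, so
per-subject SDs are `SE * sqrt(n)`. Metrics follow
`group mean + slope * (age - group mean age) + noise`, which preserves
group means for any slope; published reports give the age trends only as
significant correlations without an effect size, so the defaults
(-0.2 %/year for CCFA, +0.002/year for CV) are our plausible choices and
are free parameters, not calibrated facts. With nonzero slopes the
marginal metric SD slightly exceeds the configured residual SD; the
group-mean recovery tests run with slopes off. FAF-positive eyes get a
tile-aligned rectangle covering ~15 % of the field (7 x 7 tiles of the
18-grid; the abnormal area is described as relatively small), snapped to
tile boundaries so the injected region level is exact under the
tile-wise generator. Asymmetric eyes get a thicker-side label
(upper/lower, equal probability) and symmetric half-offsets on the outer
thirds.

### What passing tests do and do not show

The generator emulates the *statistical* structure the analysis assumes:
group-level metric differences, within-eye region and side effects, age
trends, and covariate distributions of the published cohort. It does not
model OCTA speckle or
decorrelation physics, projection artifacts, vessel morphology, or
device noise. Passing recovery tests therefore demonstrates that the
quantification and inference machinery is correct and unbiased under its
own assumptions — not that the pipeline reproduces device-specific
measurements on real slabs.

One deliberate consequence of this honesty: the full
render-then-binarize path *attenuates* tile-level heterogeneity, because
a locally adaptive threshold partially normalizes away local density
differences (measured CVs in the end-to-end demo run ~0.03-0.04 below
the latent generating values, while whole-image CCFA recovery is within
~2 pp). The CV recovery targets are therefore defined on ground-truth
binary maps, where the tile statistic's own calibration can be verified
exactly; the end-to-end demo checks determinism, classification
semantics and direction of effects rather than CV point recovery. On
real data the same caveat applies to absolute CV values, which is one
reason the published cutoffs are consumed as fixed defaults rather than
re-derived (see below).

## Statistics

Group comparisons use the Mann-Whitney U test (exact when combined
n <= 20 without ties, otherwise normal approximation with tie and
continuity corrections); within-eye comparisons use the Wilcoxon
signed-rank test (exact when n <= 15 nonzero untied differences; zero
differences dropped). Both switchovers are configurable. The FAF 2 x 2
table uses the Fisher exact test; the two-sided p follows the
minimum-likelihood convention. The published FAF comparison (9/38 vs
0/22) prints p = 0.011, which is the *one-sided* exact p (the two-sided
value is 0.020); the report carries both so either convention can be
read off.

ROC curves use the rank-formulation AUC with half-credit for ties;
cutoffs maximize the Youden index with ties broken toward higher
specificity. The CCFA ratio is scored with lower-is-positive, the CV
with higher-is-positive. The shipped risk cutoffs (58.5 %, 0.165)
remain the defaults regardless of what a synthetic ROC yields: they are
the published clinical rule, and a cutoff re-derived from synthetic data
would have no clinical meaning.

Adjusted odds ratios come from maximum-likelihood logistic regression
(IRLS, log-likelihood tolerance 1e-8) with Wald 95 % intervals.
Complete or quasi-complete separation raises an explicit error rather
than a silently huge OR; the cohort orchestrator logs such analyses as
skipped (a cohort with zero FAF-positive controls *will* skip the
group-on-FAF fit — that is the correct answer, not a failure). Because
the published phrasing is ambiguous about whether the adjusted exposure
models predict high-risk status or fellow-eye status, the report emits
both fits for FAF abnormality and vasculature asymmetry.

Parameter recovery of the logistic machinery is tested by simulation: at
n = 600 with a generating exposure OR of 5.408 plus age and sex effects,
the mean estimated OR over 100 replicates is within 10 % and Wald CI
coverage is in the 90-98 % band.

## Numerical choices and degenerate inputs

* Windowed SD uses population (n) normalization inside the threshold
  formula, per the original method; tile CV uses sample (n-1) SD.
* FFT convolution error is ~1e-12 in the moments (~1e-6 after the square
  root at near-zero variance); threshold decisions are only affected if
  an intensity sits within that distance of `T`, which has probability
  ~0 for continuous inputs.
* Ties at the threshold (`intensity == T`) are background.
* Empty masks, zero tile-ratio means, all-zero paired differences,
  degenerate 2 x 2 margins and single-class ROC labels are errors, not
  NaNs.
* All generators are bit-reproducible under a fixed seed; rendering uses
  a derived secondary seed so flow-map and intensity draws are
  independent streams.
* Report JSON embeds the config echo and package version but neither
  timestamps nor machine-specific paths, so identical config + seed
  gives byte-identical reports.

## Problem sizes used by the validation suite

The recovery tests and the acceptance script average 50 replicate
cohorts of 38 and 22 maps (540 x 540, the analyzed-field geometry) for
the group-level targets, 50 x 9 two-region maps for the FAF-region
target, and 50 x 17 banded maps for the side target, comparing each
recovered grand mean against its generating value within three standard
errors of the replicate means. These sizes mirror the published group
sizes while keeping the whole suite comfortably desk-scale.

## Known limitations

* Magnification correction implements the axial-length ratio form only;
  the full three-variable Littmann telecentric formula (keratometry,
  refraction) is out of scope, and the device's true reference axial
  length is unknown — 24.46 mm is an assumption.
* The Phansalkar window radius and parameters used by the original
  ImageJ analyses are not published; defaults follow the plugin's
  conventions and are recorded in output provenance.
* Absolute CV values depend on the binarization's local adaptation (see
  above); between-group and within-eye *contrasts* are the robust
  quantities.
* The synthetic cohort draws metrics and labels independently per
  subject; it does not model correlation between FAF abnormality and
  asymmetry within an eye beyond their separate prevalences.
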