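# choriomap

Quantification of choriocapillaris flow deficits from en-face OCT
angiography (OCTA), for retina researchers studying early, pre-clinical
changes in age-related macular degeneration (AMD) fellow eyes.

The choriocapillaris — the capillary layer feeding the retinal pigment
epithelium (RPE) — loses flow signal with age, and AMD fellow eyes show
more severe and more *heterogeneous* loss even before any visible fundus
change. choriomap turns an en-face choriocapillaris slab into two numbers
per eye and runs the associated cohort inference:

* **CCFA ratio** (%): choriocapillaris flow area over analyzed area,
  measured on a slab binarized with the Phansalkar local threshold
  `T = m (1 + p e^{-q m} + k (s/R - 1))`, where `m` and `s` are the local
  mean and SD over a circular window (defaults: radius 15 px, `k = 0.25`,
  `R = 0.5`, `p = 2`, `q = 10`).
* **CV of the CCFA ratio** (unitless): the coefficient of variation
  (sample SD / mean) of per-tile CCFA ratios over an 18 × 18 grid of
  equal tiles — a heterogeneity score for patchy flow deficits.

Around this core the package provides axial-length magnification
correction (`(AL − 1.82)/(AL_ref − 1.82)`, the ratio form of the modified
Bennett formula) with center-cropping to the analyzed 2.7 × 2.7 mm field;
region-masked comparisons (FAF-abnormal vs normal area); upper/lower-third
banding for thicker vs thinner choroidal-vasculature sides; the
dual-cutoff risk rule (high risk iff CCFA < 58.5 % **and** CV ≥ 0.165);
and cohort statistics (Mann–Whitney U, Wilcoxon signed-rank, Fisher exact,
ROC with Youden cutoffs, age/sex-adjusted logistic odds ratios).
Calibrated synthetic image and cohort generators make the whole pipeline
testable end-to-end without patient data.

## Worked example

Quantify one synthetic eye:

```r
library(choriomap)

p    <- image_gen_params(true_flow_fraction = 0.55, tile_sd = 0.09, seed = 42)
fm   <- generate_flow_map(p)                       # ground-truth binary map
slab <- render_grayscale(fm, p, axial_length = 24.1)
slab
#> slab_image: 540 x 540 px, 2.700 mm field (0.005 mm/px), axial length 24.10 mm

quantify_slab(slab)
#> ccfa_result: CCFA ratio 57.37%, CV 0.1263 (low risk)
```

The slab was generated at a true flow fraction of 55 %; the Phansalkar
recovery lands within ~2.4 percentage points. The CV scores the
heterogeneity of the 324 tile ratios. The ratio 57.37 % is below the
58.5 % cutoff, but the CV 0.126 is below 0.165, so the conjunctive risk
rule classifies the eye low risk.

Run the shipped 60-eye synthetic demo (38 AMD-fellow-like, 22
control-like, calibrated to the published cohort) end-to-end:

```r
run <- run_full_pipeline(run_config(seed = 11L))
run$cohort_result
#> cohort_result: 38 AMD fellow eyes vs 22 controls
#>   CCFA ratio group difference: p = 0.02462
#>   CV group difference:         p = 0.6731
#>   FAF 2x2 Fisher: p = 0.002279 (one-sided 0.001935)
#>   ROC: AUC 0.676 (CCFA, cutoff 60.2), 0.533 (CV, cutoff 0.150)
#>   high risk (CCFA < 58.5 & CV >= 0.165): 3 of 60 eyes
#>   skipped: logistic_group_on_highrisk, logistic_highrisk_on_faf, ...
```

Reading this: the AMD-like arm has a significantly lower CCFA ratio; the
measured CV difference is attenuated by the locally adaptive binarization
(see the vignette), high-risk eyes occur only in the AMD-like arm, and
logistic fits that would be quasi-separated (e.g. all high-risk eyes in
one arm) are skipped with a logged reason instead of reporting a
meaningless huge odds ratio. `summary(run$cohort_result)` tabulates every
p-value and odds ratio; `plot(run$per_image[[1]])` displays a tile grid.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "choriomap", package = "choriomap")` with subcommands
`simulate`, `quantify`, `cohort`, `run`.

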