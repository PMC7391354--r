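# radstab

Radiomic feature reproducibility under inter-rater segmentation variability.

Radiomic analysis turns a segmented lesion on a CT image into a vector of
quantitative features — intensity statistics, 2D shape descriptors, and
gray-level texture measures (GLCM, GLSZM, GLRLM, NGTDM). Every feature value
depends on the lesion contour, and no two raters contour alike, so part of
each feature is rater noise. radstab is for imaging scientists who need to
know *which* features survive a change of rater before putting them in a
model. It provides:

* a synthetic-lesion generator (CT-like phantoms with controllable
  contrast, texture, and boundary irregularity) plus a segmentation
  simulator that perturbs a mask through its signed distance field and is
  **calibrated by bisection to a target median pairwise Dice** — standing in
  for a panel of human experts or a probabilistic segmentation sampler;
* a radiomic extractor producing 89 features in six categories
  (18 first-order, 12 shape, 22 GLCM, 16 GLSZM, 16 GLRLM, 5 NGTDM) under a
  fixed protocol: 1 mm isotropic resampling, 25 HU fixed-bin-width
  discretisation anchored at the ROI minimum, 30 mm³ lesion eligibility,
  single-component masks only, raw (unscaled) values;
* reliability analysis with the one-way random-effects intraclass
  correlation

  $$\mathrm{ICC}(1,1) = \frac{\mathrm{MS}_B - \mathrm{MS}_W}{\mathrm{MS}_B + (k-1)\,\mathrm{MS}_W},$$

  percentile bootstrap confidence intervals (lesion resampling, 1000
  replicates), per-category summaries, stability classification under the
  0.75 and 0.9 conventions, and Pearson correlation of ICC vectors across
  rater populations.

Dice overlap is computed as $2|A \cap B| / (|A| + |B|)$; agreement is
summarised as the median and interquartile range of all pairwise scores.

Everything is tibble-in/tibble-out and pipeable; result objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(radstab)

# one lesion and a rater population calibrated to median pairwise Dice 0.87
les    <- make_lesion(lesion_preset("lung", image_size = 64), seed = 7)
params <- calibrate_amplitude(les$mask, target_median_dice = 0.87,
                              perturbation_params(corr_len = 4),
                              spacing = 1, seed = 2)
raters <- sample_rater_set(les$mask, params, k = 25, spacing = 1, seed = 3)
dice_summary(pairwise_dice(raters))
#> # A tibble: 1 × 5
#>   median iqr_low iqr_high n_pairs n_undefined
#>    <dbl>   <dbl>    <dbl>   <int>       <int>
#> 1  0.877   0.837    0.902     300           0
```

The calibrated amplitude (here 0.98 mm of boundary displacement) reproduces
the requested agreement level: the 300 pairwise Dice scores of the 25
simulated raters have median 0.877, within the ±0.02 calibration tolerance
of the 0.87 target.

```r
cohort <- simulate_cohort(20, k_raters = 25,
                          spec = lesion_preset("lung", image_size = 64),
                          params = params, seed = 11)
feats  <- extract_features(cohort)          # 500 rows x (2 + 89) columns
tab    <- icc_table(feats, n_boot = 1000, seed = 4)
category_summary(tab)
#> # A tibble: 7 × 6
#>   category   mean_icc n_features n_undefined frac_gt_0.8 frac_gt_0.9
#>   <chr>         <dbl>      <int>       <int>       <dbl>       <dbl>
#> 1 firstorder    0.285         18           0       0.167      0.111
#> 2 shape         0.838         12           0       0.917      0.167
#> 3 glcm          0.297         22           0       0          0
#> 4 glszm         0.306         16           0       0          0
#> 5 glrlm         0.378         16           0       0.125      0.0625
#> 6 ngtdm         0.186          5           0       0          0
#> 7 overall       0.377         89           0       0.180      0.0562
```

Each row of `tab` is one feature's ICC(1,1) with its bootstrap 95% CI over
the 20 lesions × 25 raters. The category summary shows the structural
result: shape features are by far the most robust to contour variation
(mean ICC 0.84; 92% above 0.8), while intensity and texture features on
this high-contrast lung phantom are fragile — including a few background
pixels at −800 HU swings them hard. On a homogeneous synthetic cohort the
absolute ICC levels sit below what heterogeneous clinical cohorts show; the
rankings and category ordering are the transferable result (see the
vignette).

`run_experiment(run_config(...))` runs the full two-population study — a
4-expert panel at within-panel Dice 0.87 and a 25-sample population at
Dice 0.85 against the experts, Dice > 0.3 acceptance — and writes feature
tables, Dice summaries, ICC tables, category summaries, the
expert-vs-sampled ICC correlation and a run manifest as CSVs/JSON.
`inst/scripts/run_pipeline.R` wraps it for the shell.

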