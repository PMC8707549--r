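# radkern

Radiomic features — quantitative descriptors of a segmented lesion's
intensity, texture and shape — are not robust to the CT reconstruction
kernel. The same tumor rendered with a smooth kernel (B30f-like: low noise,
low resolution) and a sharp kernel (B70f-like: high resolution, much more
noise) yields systematically different feature values, which confounds any
radiomics study pooling scans across scanners or sites. `radkern` implements
a full harmonization study around one remedy: a residual convolutional
network that converts images from one kernel rendering to the other, plus
the two evaluations that justify it.

The package provides:

* **`simcohort`** — a synthetic paired-kernel cohort generator. Each patient
  is a lung-like phantom with one textured spherical lesion rendered under
  two kernels, modeled as radial frequency responses
  `R(f) = 1 + g·(f/f_c)² / (1 + (f/f_c)²)` plus Gaussian noise, with a
  binary label that shifts the lesion texture (the stand-in for a mutation
  status). Nothing downstream requires patient data.
* **converter** — a residual fully convolutional 2D network
  (`output = input + predicted residual`, zero-initialized final layer so
  the untrained network is the exact identity), trained slice-wise with Adam
  on the sum-of-squares loss; `rmse_reduction()` quantifies conversion
  quality.
* **radiomic feature extractor** — 11 families (shape, intensity, GLCM,
  GLRLM, GLSZM, NGTDM, Laplacian-of-Gaussian, gradient/edge, Laws, Haar
  wavelet, boundary sharpness), 58 core / 89 extended named features with
  explicit undefined flags.
* **reproducibility** — per-feature Lin's concordance correlation
  coefficient, `ccc = 2·s_xy / (s_x² + s_y² + (μ_x − μ_y)²)`, with grouped
  summaries and the fraction of features above a reproducibility threshold
  (CCC > 0.85).
* **mixed-group prediction** — each patient randomly contributes one kernel
  arm (mimicking heterogeneous multi-center data); every feature is scored
  by univariate AUC (normalized Mann–Whitney U, orientation-corrected to
  `max(A, 1 − A)`) before and after harmonizing the mixed cohort, with paired
  Wilcoxon signed-rank comparisons across features.
* **statistical tests** — a Wilcoxon signed-rank implementation with an
  exact small-sample mode (full sign-pattern null distribution), plus ANOVA
  and t-test wrappers.

Results are tibbles with `tidy()` / `glance()` / `autoplot()` methods, and a
thin CLI (`exec/radkern`) exposes each stage as a file-in/file-out
subcommand.

## Worked example

Generate a small paired-kernel cohort, extract features from both
renderings, and measure their reproducibility:

```r
library(radkern)

smooth <- kernel_profile("smooth", mtf_gain = -0.6, mtf_cutoff = 0.20,
                         noise_sigma = 10)
sharp  <- kernel_profile("sharp",  mtf_gain =  1.5, mtf_cutoff = 0.20,
                         noise_sigma = 40)
cohort <- generate_cohort(n = 8, prevalence = 0.5, spec = phantom_spec(),
                          smooth = smooth, sharp = sharp, seed = 7)

tab_smo <- extract_cohort_features(cohort, "smooth")
tab_shp <- extract_cohort_features(cohort, "sharp")
ccc_table(tab_smo, tab_shp, registry = feature_registry("core"))
#> <ccc_report> ori_smo vs ori_shp: 58 features (57 defined)
#>   CCC mean 0.463 +/- 0.414, median 0.409, fraction > 0.85: 0.333
```

Between the two *original* renderings agreement is mediocre and wildly
uneven across features: the kernel, not the biology, dominates many texture
values. The block of features above 0.85 is led by the shape family — the
lesion mask is shared across kernels, so shape is perfectly reproducible by
construction — while noise-sensitive texture features fall near zero.

The full two-phase experiment — train converters on a development cohort,
evaluate reproducibility and label prediction on a disjoint validation
cohort rendered with shifted kernel parameters — is one call:

```r
report <- run_experiment(experiment_config(seed = 1))
report
#> <experiment_report> development n = 16, validation n = 60 (seed 1)
#>   mean RMSE reduction: 72.8% (to smooth), 21.9% (to sharp)
#>   CCC summary:
#>     ori_smo vs ori_shp     mean 0.383 +/- 0.380, median 0.190, fraction > 0.85: 0.155
#>     ori_smo vs conv_smo    mean 0.837 +/- 0.194, median 0.898, fraction > 0.85: 0.586
#>     ori_shp vs conv_shp    mean 0.903 +/- 0.135, median 0.980, fraction > 0.85: 0.719
#> <auc_report> univariate AUC by mixed group
#>   ori_mix       median 0.536 +/- 0.018 MAD (n = 58 features)
#>   conv_mix_smo  median 0.552 +/- 0.037 MAD (n = 58 features)
#>   conv_mix_shp  median 0.548 +/- 0.036 MAD (n = 58 features)
#>   conv_mix_smo vs ori_mix: Z = 2.21, p = 0.0272
#>   conv_mix_shp vs ori_mix: Z = 2.10, p = 0.0353
```

Reading the report: conversion moves images close to their target rendering
(large RMSE reduction toward smooth; the sharp direction is intrinsically
harder since it must restore high-frequency content against a noisier
target). Feature reproducibility jumps — the mean CCC rises from 0.38 to
0.84/0.90, and the fraction of highly reproducible features (CCC > 0.85)
from 16% to 59%/72%, with paired signed-rank p-values far below 0.001. On
the mixed-kernel cohort, harmonizing the cohort raises the median
univariate AUC for predicting the synthetic label (paired signed-rank
across features), with the larger gain for the smooth target.

`write_report(report, "out/")` serializes every table plus a JSON summary;
`autoplot(report$ccc_reports[[1]])` and `autoplot(report$auc_report)` draw
the reproducibility dot plot and the AUC boxplots.

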