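---
title: "Methods: CT kernel harmonization for reproducible radiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT kernel harmonization for reproducible radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A CT scan is reconstructed with a convolution kernel chosen at the console.
"Smooth" kernels (B30f and relatives) suppress noise and high spatial
frequencies; "sharp" kernels (B70f and relatives) preserve edges at the cost
of markedly noisier images. Radiomic features — quantitative descriptors of a
segmented lesion's intensity, texture and shape — are sensitive to that
choice, so cohorts pooled across scanners and sites mix two renderings of the
same anatomy that yield systematically different feature values. `radkern`
implements one remedy end to end: a residual convolutional network that
converts images from one kernel rendering to the other, plus the two
evaluations that justify it — feature reproducibility measured by Lin's
concordance correlation coefficient (CCC), and univariate label-prediction
AUC on deliberately mixed-kernel cohorts.

Everything runs on synthetic cohorts generated by the package itself, so the
whole analysis is testable without patient data; real NIfTI volumes with
lesion masks drop into the same functions.

## The synthetic cohort model

`generate_cohort()` draws per-patient phantoms: a uniform lung-like
background (default -800 HU) containing one spherical lesion (default radius
5 voxels in a 64 x 64 x 24 grid at 1 mm spacing) whose interior carries a
stationary correlated Gaussian texture. The texture is white noise smoothed
to a correlation length (default 1.5 voxels) by periodic Gaussian filtering
and scaled to a marginal standard deviation `texture_contrast` (default
60 HU). A binary label — the stand-in for a mutation status — multiplies
contrast and correlation length by `label_effect` (default 1.5), so texture
features carry a discriminative signal of realistic subtlety: individual
feature AUCs land well below 1, as in real biomarker screens.

A reconstruction kernel is modeled as a radially symmetric frequency
response applied slice-wise in 2D Fourier space,

$$R(f) = 1 + g\,\frac{(f/f_c)^2}{1 + (f/f_c)^2},$$

followed by additive white Gaussian noise. The ramp is 0 at DC (mean
intensity is always preserved) and saturates at 1, so `mtf_gain` $g$ is the
asymptotic high-frequency boost ($g < 0$ attenuates, as smooth kernels do)
and `mtf_cutoff` $f_c$ (cycles/voxel) sets the transition scale. This is the
minimal model that reproduces the defining trade-off — sharp kernels buy
resolution with noise — while staying fully parameterized: vendor kernels are
not published as formulas, so the ramp's parameters are configuration, not
fact. Defaults: smooth = gain -0.6, cutoff 0.20, noise sd 10 HU; sharp =
gain +1.5, cutoff 0.20, noise sd 40 HU. The validation cohort in
`experiment_config()` deliberately shifts cutoff and noise (0.22/12 and
0.18/45) to emulate applying a trained converter on a different scanner.

What the generator does *not* emulate: projection-domain physics (no
sinograms or filtered back-projection), anatomical background structure,
multi-lesion patients, or segmentation variability (the mask is shared
exactly across renderings, which is also what makes shape features exactly
reproducible). Passing tests on this cohort therefore demonstrate that the
pipeline's statistics behave as designed under a faithful noise/resolution
model — not that the converter handles real anatomy.

Determinism: every record's seed is derived from the master seed by an
integer hash (`seed`, stage tag, record index), so cohorts regenerate
bit-identically and independently of evaluation order.

## The kernel converter

`build_converter()` constructs a residual, fully convolutional 2D network:
`n_layers` 3 x 3 convolutions (rectifier nonlinearities on all but the
last, which maps back to one channel), and the output is input + predicted
residual. The final layer is zero-initialized, making the untrained network
the exact identity — a useful property both numerically (conversion can only
move an image away from itself by training) and for testing. Slices are
normalized as `(x + 800) / 1000` so lung background sits near 0 on a
unit-ish scale; the constants are stored with the model. Training minimizes
the sum-of-squares loss (reported as per-pixel mean, which differs only by a
constant factor) with Adam. The default optimizer recipe is learning rate
1e-4 for 55 epochs. The architecture depth and width are genuinely open
choices — published kernel-conversion networks of this type vary in both —
so they are fully configurable: the default is 6 layers x 64 channels, and
the desk-scale experiment preset uses 4 layers x 8 channels with learning
rate 1e-3 for 20 epochs on 128 slice pairs, sizes chosen once so that a full
two-phase experiment runs in minutes on one CPU while the converter still
reaches a small fraction of its initial held-out loss. Batch size defaults
to 8 slices and is plain configuration. Two independent models are trained,
one per direction; no weights are shared.

The forward/backward passes are implemented as im2col matrices multiplied by
weight matrices, so all heavy computation is BLAS matrix multiplication;
training is deterministic given the config seed (initialization, train/test
split and batch order all derive from it).

Quality check: `rmse()` and `rmse_reduction()` quantify how much closer the
converted image sits to the target rendering than the source did
(`100 * (1 - rmse(conv, target)/rmse(src, target))`).

## The feature extractor

`extract_all()` computes 11 families over a masked lesion. Choices that the
field leaves open, fixed here and recorded in the extractor version:

* **Quantization**: equal-width bins over the in-mask range; 32 levels for
  the primary texture matrices, 16 for the `_q16` variants of the extended
  registry. A constant ROI maps to level 1.
* **GLCM**: 13 unique 3D unit offsets at distance 1, symmetric accumulation,
  pairs fully inside the mask, pooled into one matrix (not averaged per
  direction). Entropies in bits.
* **GLRLM**: runs confined to the mask; features computed per direction and
  averaged over the 13 directions. `Run_SPE` is short-run emphasis,
  `Run_PP` is runs per in-mask voxel.
* **GLSZM**: 26-connected same-level zones. Note a corollary worth knowing:
  under 26-connectivity a two-level checkerboard is diagonally connected and
  collapses into two zones, so "many zones" requires many distinct levels,
  not alternation.
* **NGTDM**: Amadasun's statistics over voxels whose complete
  26-neighborhood lies in the mask; coarseness is `1/(1e-12 + sum(p_i s_i))`
  capped at `1e12`.
* **LoG**: DC-corrected Laplacian-of-Gaussian kernels truncated at 4 sigma,
  sigmas 1.5 and 2.5 voxels by default (a third scale for the extended
  registry); the `pk` suffix indexes the sigma list. In-mask responses are
  summarized by 64-bin Shannon entropy (a constant response is entropy 0 by
  the single-bin rule), mean and sd.
* **EdgeFreq**: defined here as the mean (and sd) of the central-difference
  gradient magnitude over the mask; edge-frequency features appear under
  several non-equivalent definitions in the literature, so this package
  fixes a transparent one.
* **Sharpness**: logistic profiles fitted along 26 radial rays from the mask
  centroid; the feature is the mean maximum slope `b/(4s)` over successful
  fits, undefined with fewer than 3.
* **Laws / wavelet**: separable L5/E5/S5 energy means with edge-replication
  padding; one-level 3D Haar subband mean absolute coefficients over the
  downsampled mask support (bounding box of at least 8 voxels per axis
  required).

A feature that cannot be computed carries an explicit `NA` "undefined" flag
rather than a silent zero, and flags propagate through tables, CSV round
trips and CCC summaries (which drop flagged pairs and record the remaining
n). The `"core"` registry holds 58 features; `"extended"` adds quantization
and scale variants for 89 features in 23 groups, mirroring the scale of a
development-cohort analysis. Group membership is an editable tibble, not a
standard.

## Reproducibility and prediction analyses

`ccc()` implements Lin's estimator with population (1/n) moments — the
choice matters at small n and follows Lin's original definition. A zero
denominator (both vectors constant and equal) is undefined, flagged and
excluded from summaries with its count reported. `fraction_high()` uses
strict `> 0.85`. `grouped_ccc()` averages defined entries per registry
group, the tabular analog of the grouped reproducibility heatmap.

`assign_mixed()` splits a cohort into smooth/sharp arms differing by at most
one patient; `mix_feature_tables()` assembles `ori_mix`, `conv_mix_smo` and
`conv_mix_shp` from the four per-setting tables without re-extracting
features. `univariate_auc()` is the normalized Mann-Whitney U with midrank
ties; reported AUCs are orientation-corrected to `max(A, 1 - A)` (the
direction-agnostic convention of univariate screens, toggleable via
`orientation_correct`). Group distributions are summarized by median and
unscaled median absolute deviation, and converted groups are compared
against `ori_mix` by the paired two-tailed Wilcoxon signed-rank test across
features.

`wilcoxon_signed_rank()` drops zero differences (Wilcoxon's rule, count
reported), uses midranks, and offers an exact mode — the null distribution
of W over all 2^n sign patterns, computed by dynamic programming over
doubled midranks, which is mathematically identical to enumeration — plus a
normal approximation with tie correction and 0.5 continuity correction. The
`auto` rule uses exact for n <= 25 without ties; feature-scale comparisons
(dozens to hundreds of features) use the approximation, which is what makes
the reported Z statistics comparable across runs. ANOVA and two-sample t
tests wrap the standard `stats` implementations with explicit flagging of
zero-variance degeneracies.

## The experiment driver

`run_experiment()` executes both phases on disjoint cohorts: train
converters on the development cohort, then evaluate reproducibility and
prediction on the validation cohort rendered under shifted kernel
parameters. The desk preset uses 16 development and 60 validation patients
at 50% label prevalence; the `"study"` preset scales to 32 development and
223 validation patients at prevalence 114/223 with the full training recipe. All stage seeds derive
from one master seed and the run is a pure function of its config: two runs
produce byte-identical CSV/JSON reports, which is itself a tested property.
`write_report()` emits per-feature CCC tables, grouped means, signed-rank
tests, per-feature AUCs, the top-3 feature table (ranked by
converted-to-smooth AUC, joined with the three CCC comparisons), RMSE
reductions, training logs and a JSON summary.

## Known limitations

* The kernel model is a frequency-domain stand-in; no claim is made that its
  parameters match any vendor kernel's MTF.
* DICOM series input is not implemented (no R DICOM reader in the supported
  dependency set); volumes enter as NIfTI or in-memory arrays.
* The extractor predates no standard: it is deliberately *not* IBSI-certified,
  and the named-feature definitions fixed above are this package's own.
* Only univariate prediction is evaluated; multivariate models are out of
  scope.
* Sharp-direction conversion is intrinsically harder (it must hallucinate
  high-frequency content and match a noisier target), and its RMSE gain is
  correspondingly smaller — visible in the reported per-direction RMSE
  reductions.
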