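Package: radkern
Title: Harmonizing CT Reconstruction Kernels for Reproducible Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study and correct the effect of CT reconstruction
    kernels on radiomic features. Provides a synthetic paired-kernel cohort
    generator (smooth vs sharp renderings of the same anatomy with labeled
    lesions), a residual convolutional network that converts images between
    kernel renderings, a radiomic feature extractor covering shape,
    intensity, texture-matrix (GLCM, GLRLM, GLSZM, NGTDM), Laplacian of
    Gaussian, edge, Laws, wavelet and sharpness families, Lin's concordance
    correlation coefficient for feature reproducibility, univariate AUC
    screening on mixed-kernel cohorts, and the Wilcoxon signed-rank, ANOVA
    and t tests used to compare them. An experiment driver reproduces the
    full harmonization study end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
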