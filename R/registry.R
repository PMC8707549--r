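#' The radiomic feature registry
#'
#' Every feature the extractor can compute, with its family and its group id
#' (used for grouped reproducibility summaries, e.g. heatmap rows). The
#' `"core"` preset holds 58 features spanning all 11 families; the
#' `"extended"` preset adds texture variants at a coarser 16-level
#' quantization, a third LoG scale, extra Laws masks and intensity
#' percentiles for a total of 89 features in 23 groups. The grouping is a
#' package configuration, not a fixed standard: pass your own registry tibble
#' (columns `feature`, `family`, `group`) anywhere one is accepted.
#'
#' @param preset `"core"` or `"extended"`.
#' @return A tibble with columns `feature`, `family`, `group`.
#' @export
feature_registry <- function(preset = c("core", "extended")) {
  preset <- match.arg(preset)
  reg <- function(features, family, group) {
    tibble(feature = features, family = family, group = group)
  }
  core <- dplyr::bind_rows(
    reg(c("Shape_Volume_mm3", "Shape_SurfaceArea_mm2",
          "Shape_MaxDiameter3D_mm"), "shape", 1L),
    reg(c("Shape_Compactness", "Shape_Sphericity",
          "Shape_SurfaceToVolumeRatio"), "shape", 2L),
    reg(c("Intensity_Mean", "Intensity_Median"), "intensity", 3L),
    reg(c("Intensity_SD", "Intensity_IQR", "Intensity_Range",
          "Intensity_Energy"), "intensity", 4L),
    reg(c("Intensity_Skewness_2D", "Intensity_Skewness_3D",
          "Intensity_Kurtosis", "Intensity_Entropy"), "intensity", 5L),
    reg(c("GLCM_Entropy", "GLCM_Diff_Entropy", "GLCM_Sum_Entropy",
          "GLCM_Contrast", "GLCM_Homogeneity", "GLCM_Energy",
          "GLCM_Correlation"), "glcm", 6L),
    reg(c("Run_SPE", "Run_LRE", "Run_PP", "Run_GLN", "Run_RLN"), "glrlm", 7L),
    reg(c("SizeZone_SZE", "SizeZone_LZE", "SizeZone_ZP", "SizeZone_GLN"),
        "glszm", 8L),
    reg(c("NGTDM_Coarseness", "NGTDM_Busyness", "NGTDM_Contrast",
          "NGTDM_Complexity"), "ngtdm", 9L),
    reg(c("LoG_Entropy_p1", "LoG_Mean_p1", "LoG_SD_p1"), "log", 10L),
    reg(c("LoG_Entropy_p2", "LoG_Mean_p2", "LoG_SD_p2"), "log", 11L),
    reg(c("EdgeFreq_Mean", "EdgeFreq_SD"), "edge", 12L),
    reg(c("Laws_L5L5L5", "Laws_E5E5E5", "Laws_S5S5S5", "Laws_L5E5E5",
          "Laws_L5S5S5"), "laws", 13L),
    reg("Wavelet_LLL", "wavelet", 14L),
    reg(c("Wavelet_HLL", "Wavelet_LHL", "Wavelet_HHL", "Wavelet_LLH",
          "Wavelet_HLH", "Wavelet_LHH", "Wavelet_HHH"), "wavelet", 15L),
    reg("Sigmoid_Slope", "sharpness", 16L)
  )
  if (preset == "core") return(core)
  glcm16 <- paste0(c("GLCM_Entropy", "GLCM_Diff_Entropy", "GLCM_Sum_Entropy",
                     "GLCM_Contrast", "GLCM_Homogeneity", "GLCM_Energy",
                     "GLCM_Correlation"), "_q16")
  glrlm16 <- paste0(c("Run_SPE", "Run_LRE", "Run_PP", "Run_GLN", "Run_RLN"),
                    "_q16")
  glszm16 <- paste0(c("SizeZone_SZE", "SizeZone_LZE", "SizeZone_ZP",
                      "SizeZone_GLN"), "_q16")
  ngtdm16 <- paste0(c("NGTDM_Coarseness", "NGTDM_Busyness", "NGTDM_Contrast",
                      "NGTDM_Complexity"), "_q16")
  dplyr::bind_rows(
    core,
    reg(glcm16, "glcm", 17L),
    reg(glrlm16, "glrlm", 18L),
    reg(glszm16, "glszm", 19L),
    reg(ngtdm16, "ngtdm", 20L),
    reg(c("LoG_Entropy_p3", "LoG_Mean_p3", "LoG_SD_p3"), "log", 21L),
    reg(paste0("Laws_", c("E5S5L5", "S5L5L5", "E5E5L5", "S5S5E5", "L5L5E5")),
        "laws", 22L),
    reg(c("Intensity_P10", "Intensity_P75", "Intensity_P90"),
        "intensity", 23L)
  )
}

#' Configure the feature extractor
#'
#' @param preset Registry preset, `"core"` (58 features) or `"extended"`
#'   (89 features; mirrors the scale of a development-cohort analysis).
#' @param n_levels Gray levels for the primary texture-matrix quantization.
#' @param n_levels_alt Gray levels for the `_q16` texture variants (extended
#'   preset only).
#' @param sigmas LoG scales in voxels; the third entry is only used by the
#'   extended preset.
#' @param registry Optional custom registry tibble overriding the preset.
#' @return An `extractor_config` object.
#' @export
extractor_config <- function(preset = c("core", "extended"),
                             n_levels = 32L, n_levels_alt = 16L,
                             sigmas = c(1.5, 2.5, 3.5),
                             registry = NULL) {
  preset <- match.arg(preset)
  reg <- registry %||% feature_registry(preset)
  stopifnot(all(c("feature", "family", "group") %in% names(reg)))
  if (anyDuplicated(reg$feature)) abort("duplicate feature names in registry")
  structure(
    list(preset = preset, n_levels = as.integer(n_levels),
         n_levels_alt = as.integer(n_levels_alt), sigmas = sigmas,
         registry = reg, version = "radkern-extractor-1"),
    class = "extractor_config"
  )
}

# Compute one family block, converting any error into undefined flags so a
# single degenerate family never aborts the whole vector.
safely_block <- function(names_out, expr) {
  res <- tryCatch(expr, error = function(e) {
    out <- rep(NA_real_, length(names_out))
    names(out) <- names_out
    out
  })
  res[names_out]
}

#' Extract every registered feature from one lesion
#'
#' Runs all feature families in the extractor's registry over the masked
#' lesion and returns a complete feature vector. Identical inputs give
#' bit-identical outputs; per-feature failures surface as `NA` (the
#' undefined flag) without aborting the remaining features.
#'
#' @param volume A `ct_volume` or 3D array.
#' @param mask A `lesion_mask` or logical array of the same shape.
#' @param config An [extractor_config()].
#' @return A tibble with columns `feature`, `family`, `group`, `value`
#'   (NA = undefined), carrying the extractor version as an attribute.
#' @export
extract_all <- function(volume, mask, config = extractor_config()) {
  stopifnot(inherits(config, "extractor_config"))
  reg <- config$registry
  vals <- c()
  need <- function(fam) any(reg$family == fam)

  if (need("shape")) {
    sp <- if (inherits(mask, "lesion_mask")) mask$spacing else volume_spacing(volume)
    fs <- grep("^Shape_", reg$feature, value = TRUE)
    vals <- c(vals, safely_block(fs, shape_features(mask, spacing = sp)))
  }
  if (need("intensity")) {
    fs <- grep("^Intensity_", reg$feature, value = TRUE)
    vals <- c(vals, safely_block(fs, intensity_features(volume, mask)))
  }
  q_main <- NULL
  q_alt <- NULL
  main_feats <- reg$feature[!grepl("_q16$", reg$feature)]
  alt_feats <- reg$feature[grepl("_q16$", reg$feature)]
  tex_fams <- c("glcm", "glrlm", "glszm", "ngtdm")
  if (any(reg$family %in% tex_fams)) {
    q_main <- tryCatch(quantize_roi(volume, mask, config$n_levels),
                       error = function(e) NULL)
    if (length(alt_feats)) {
      q_alt <- tryCatch(quantize_roi(volume, mask, config$n_levels_alt),
                        error = function(e) NULL)
    }
  }
  tex_block <- function(q, fn, prefix, suffix = "") {
    fs <- grep(prefix, if (suffix == "") main_feats else alt_feats, value = TRUE)
    if (!length(fs)) return(NULL)
    if (is.null(q)) {
      out <- rep(NA_real_, length(fs)); names(out) <- fs
      return(out)
    }
    raw <- safely_block(sub("_q16$", "", fs), fn(q))
    names(raw) <- paste0(names(raw), suffix)
    raw[fs]
  }
  vals <- c(vals,
            tex_block(q_main, glcm_features, "^GLCM_"),
            tex_block(q_main, glrlm_features, "^Run_"),
            tex_block(q_main, glszm_features, "^SizeZone_"),
            tex_block(q_main, ngtdm_features, "^NGTDM_"),
            tex_block(q_alt, glcm_features, "^GLCM_", "_q16"),
            tex_block(q_alt, glrlm_features, "^Run_", "_q16"),
            tex_block(q_alt, glszm_features, "^SizeZone_", "_q16"),
            tex_block(q_alt, ngtdm_features, "^NGTDM_", "_q16"))
  if (need("log")) {
    fs <- grep("^LoG_", reg$feature, value = TRUE)
    k_used <- sort(unique(as.integer(sub(".*_p", "", fs))))
    for (k in k_used) {
      fs_k <- fs[endsWith(fs, paste0("_p", k))]
      vals <- c(vals, safely_block(fs_k, {
        raw <- log_features(volume, mask, sigmas = config$sigmas[k])
        names(raw) <- sub("_p1$", paste0("_p", k), names(raw))
        raw
      }))
    }
  }
  if (need("edge")) {
    fs <- grep("^EdgeFreq_", reg$feature, value = TRUE)
    vals <- c(vals, safely_block(fs, edge_freq_features(volume, mask)))
  }
  if (need("laws")) {
    fs <- grep("^Laws_", reg$feature, value = TRUE)
    combos <- sub("^Laws_", "", fs)
    vals <- c(vals, safely_block(fs, laws_features(volume, mask, combos = combos)))
  }
  if (need("wavelet")) {
    fs <- grep("^Wavelet_", reg$feature, value = TRUE)
    vals <- c(vals, safely_block(fs, wavelet_features(volume, mask)))
  }
  if (need("sharpness")) {
    vals <- c(vals, safely_block(
      "Sigmoid_Slope", c(Sigmoid_Slope = sigmoid_slope(volume, mask))))
  }

  out <- reg
  out$value <- unname(vals[reg$feature])
  attr(out, "extractor_version") <- config$version
  out
}

#' Build a feature table (patients x features) for one kernel setting
#'
#' @param volumes Named list of `ct_volume`s (names are patient ids).
#' @param masks Named list of `lesion_mask`s aligned with `volumes`.
#' @param config An [extractor_config()].
#' @param setting Label for the kernel setting, e.g. `"ori_smo"`.
#' @return A tibble with `patient_id` plus one column per registered feature
#'   (NA cells are undefined flags); the setting label is stored in the
#'   `"setting"` attribute.
#' @export
extract_feature_table <- function(volumes, masks, config = extractor_config(),
                                  setting = "unknown") {
  stopifnot(length(volumes) == length(masks), length(volumes) >= 1)
  ids <- names(volumes) %||% sprintf("P%03d", seq_along(volumes))
  rows <- purrr::map(seq_along(volumes), function(i) {
    fv <- extract_all(volumes[[i]], masks[[i]], config)
    vals <- as.list(fv$value)
    names(vals) <- fv$feature
    dplyr::bind_cols(tibble(patient_id = ids[i]), tibble::as_tibble(vals))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "setting") <- setting
  out
}

#' Extract a feature table from a cohort's renderings
#'
#' @param cohort A `kernel_cohort`.
#' @param which One of `"smooth"`, `"sharp"` or `"truth"` — which rendering
#'   to extract features from.
#' @param config An [extractor_config()].
#' @param setting Optional setting label; defaults to `ori_smo` / `ori_shp` /
#'   `truth`.
#' @return A feature table tibble (see [extract_feature_table()]).
#' @export
extract_cohort_features <- function(cohort, which = c("smooth", "sharp", "truth"),
                                    config = extractor_config(),
                                    setting = NULL) {
  stopifnot(inherits(cohort, "kernel_cohort"))
  which <- match.arg(which)
  field <- switch(which, smooth = "smooth_image", sharp = "sharp_image",
                  truth = "truth")
  setting <- setting %||% switch(which, smooth = "ori_smo", sharp = "ori_shp",
                                 truth = "truth")
  vols <- purrr::map(cohort$records, field)
  masks <- purrr::map(cohort$records, "mask")
  names(vols) <- names(masks) <- vapply(cohort$records, `[[`, character(1), "id")
  extract_feature_table(vols, masks, config, setting = setting)
}

feature_table_setting <- function(tab) attr(tab, "setting") %||% "unknown"

feature_columns <- function(tab) setdiff(names(tab), "patient_id")

#' Write / read a feature table as CSV
#'
#' CSV round-trips preserve column order, patient ids, and undefined flags
#' (empty cells read back as NA).
#'
#' @param tab A feature table tibble.
#' @param path CSV path.
#' @return `write_feature_table()`: the path, invisibly.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @param setting Setting label to attach on read.
#' @return `read_feature_table()`: the feature table tibble.
#' @export
read_feature_table <- function(path, setting = "unknown") {
  if (!file.exists(path)) abort(sprintf("no such feature table: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("NA", ""))
  if (!"patient_id" %in% names(df)) {
    abort(sprintf("malformed feature table (no patient_id column): %s", path))
  }
  out <- as_tibble(df)
  out$patient_id <- as.character(out$patient_id)
  attr(out, "setting") <- setting
  out
}
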