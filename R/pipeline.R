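#' Volume I/O (NIfTI)
#'
#' Volumes round-trip through NIfTI at float32 precision with exact spacing.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()`: a `ct_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such volume: %s", path))
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    abort(sprintf("failed to read %s: %s", path, conditionMessage(e)))
  })
  vals <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)
  new_ct_volume(vals, sp[seq_len(min(3, length(sp)))])
}

#' @rdname read_volume
#' @param volume A `ct_volume` or 3D array.
#' @return `write_volume()`: the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  vals <- volume_values(volume)
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- volume_spacing(volume)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Save / load a kernel converter
#'
#' Single-file serialization of the weights together with the full
#' configuration (including the intensity normalization constants).
#'
#' @param model A `kernel_converter`.
#' @param path Destination file.
#' @return `load_converter()`: the `kernel_converter`.
#' @export
save_converter <- function(model, path) {
  stopifnot(inherits(model, "kernel_converter"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_converter
#' @export
load_converter <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such model file: %s", path))
  model <- readRDS(path)
  if (!inherits(model, "kernel_converter")) {
    abort(sprintf("%s is not a kernel converter", path))
  }
  model
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `manifest.csv` and the NIfTI volumes.
#' @return A `kernel_cohort` (generation parameters restored from the JSON
#'   sidecar when present).
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) abort(sprintf("no manifest.csv under %s", dir))
  mf <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  records <- purrr::map(seq_len(nrow(mf)), function(i) {
    mask_vol <- read_volume(mf$mask[i])
    list(
      id = as.character(mf$patient_id[i]),
      truth = read_volume(mf$truth[i]),
      smooth_image = read_volume(mf$smooth[i]),
      sharp_image = read_volume(mf$sharp[i]),
      mask = structure(list(values = mask_vol$values > 0.5,
                            spacing = mask_vol$spacing),
                       class = "lesion_mask"),
      label = as.integer(mf$label[i])
    )
  })
  gp_path <- file.path(dir, "generation_params.json")
  gp <- if (file.exists(gp_path)) jsonlite::read_json(gp_path) else list()
  structure(list(records = records, generation_params = gp),
            class = "kernel_cohort")
}

#' Configure a full harmonization experiment
#'
#' Bundles everything [run_experiment()] needs: the synthetic cohort
#' parameters for the development cohort (used to train the converters) and
#' the validation cohort (evaluated for reproducibility and label
#' prediction), the two directions' training settings, the feature registry
#' preset, and the analysis seeds — all derived from one master seed.
#'
#' The development and validation cohorts deliberately use slightly different
#' kernel parameters (cutoff and noise), emulating validation on a scanner
#' the converter never saw. The `"desk"` preset keeps cohort sizes and
#' network width small enough for interactive runs; `"study"` scales the
#' cohorts to 32/223 patients with a 114/223 label prevalence and the full
#' training recipe (6 layers, 64 channels, learning rate 1e-4, 55 epochs).
#'
#' @param preset `"desk"` or `"study"`.
#' @param seed Master seed; every stage seed is derived from it.
#' @param dev_n,val_n Cohort sizes (preset defaults: 16/60 desk, 32/223
#'   study).
#' @param prevalence Positive-label fraction of both cohorts.
#' @param spec A [phantom_spec()].
#' @param dev_smooth,dev_sharp,val_smooth,val_sharp [kernel_profile()]s.
#' @param n_layers,channels,learning_rate,n_epochs,batch_size Converter
#'   training settings (see [converter_config()]).
#' @param train_slices Axial slices per development patient used as training
#'   pairs.
#' @param holdout_fraction Held-out fraction of training pairs.
#' @param preset_registry Feature registry preset (`"core"` or
#'   `"extended"`).
#' @param ccc_threshold Reproducibility threshold for fraction-high
#'   reporting.
#' @param top_k Top-feature table size.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(preset = c("desk", "study"),
                              seed = 20231L,
                              dev_n = NULL, val_n = NULL, prevalence = NULL,
                              spec = phantom_spec(),
                              dev_smooth = kernel_profile("smooth", -0.6, 0.20, 10),
                              dev_sharp = kernel_profile("sharp", 1.5, 0.20, 40),
                              val_smooth = kernel_profile("smooth", -0.6, 0.22, 12),
                              val_sharp = kernel_profile("sharp", 1.5, 0.18, 45),
                              n_layers = NULL, channels = NULL,
                              learning_rate = NULL, n_epochs = NULL,
                              batch_size = 8L,
                              train_slices = 9:16,
                              holdout_fraction = 0.25,
                              preset_registry = "core",
                              ccc_threshold = 0.85,
                              top_k = 3L) {
  preset <- match.arg(preset)
  full <- preset == "study"
  structure(
    list(
      preset = preset, seed = as.integer(seed),
      dev_n = dev_n %||% (if (full) 32L else 16L),
      val_n = val_n %||% (if (full) 223L else 60L),
      prevalence = prevalence %||% (if (full) 114 / 223 else 0.5),
      spec = spec,
      dev_smooth = dev_smooth, dev_sharp = dev_sharp,
      val_smooth = val_smooth, val_sharp = val_sharp,
      n_layers = n_layers %||% (if (full) 6L else 4L),
      channels = channels %||% (if (full) 64L else 8L),
      learning_rate = learning_rate %||% (if (full) 1e-4 else 1e-3),
      n_epochs = n_epochs %||% (if (full) 55L else 20L),
      batch_size = as.integer(batch_size),
      train_slices = train_slices,
      holdout_fraction = holdout_fraction,
      preset_registry = preset_registry,
      ccc_threshold = ccc_threshold,
      top_k = as.integer(top_k)
    ),
    class = "experiment_config"
  )
}

#' Run the full kernel-harmonization experiment
#'
#' Two phases on disjoint synthetic cohorts. Development phase: generate the
#' development cohort, train the sharp-to-smooth and smooth-to-sharp
#' converters on its paired slices, and record the RMSE quality check.
#' Validation phase: generate the validation cohort under shifted kernel
#' parameters, convert every patient both ways, extract the four feature
#' tables (ori_smo / ori_shp / conv_smo / conv_shp), compute the three CCC
#' comparisons with paired signed-rank tests, the fraction of features above
#' the reproducibility threshold, the group-averaged CCC table, and the
#' mixed-group univariate AUC analysis against the synthetic labels.
#'
#' The entire run is a pure function of the config: rerunning with the same
#' config reproduces the report bit-identically.
#'
#' @param config An [experiment_config()].
#' @return An `experiment_report` list; see [write_report()].
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed

  dev <- generate_cohort(config$dev_n, config$prevalence, config$spec,
                         config$dev_smooth, config$dev_sharp,
                         derive_seed(seed, "dev"))
  val <- generate_cohort(config$val_n, config$prevalence, config$spec,
                         config$val_smooth, config$val_sharp,
                         derive_seed(seed, "val"))

  converters <- list()
  for (dir in c("to_smooth", "to_sharp")) {
    cfg <- converter_config(
      direction = dir, n_layers = config$n_layers, channels = config$channels,
      learning_rate = config$learning_rate, n_epochs = config$n_epochs,
      batch_size = config$batch_size, seed = derive_seed(seed, dir)
    )
    pairs <- cohort_slice_pairs(dev, dir, slices = config$train_slices)
    converters[[dir]] <- train_converter(pairs, cfg,
                                         holdout_fraction = config$holdout_fraction)
  }

  ids <- vapply(val$records, `[[`, character(1), "id")
  masks <- purrr::map(val$records, "mask")
  smo <- purrr::map(val$records, "smooth_image")
  shp <- purrr::map(val$records, "sharp_image")
  names(masks) <- names(smo) <- names(shp) <- ids
  conv_smo <- purrr::map(shp, ~convert_volume(converters$to_smooth, .x))
  conv_shp <- purrr::map(smo, ~convert_volume(converters$to_sharp, .x))

  rmse_tab <- tibble(
    patient_id = ids,
    reduction_to_smooth = purrr::map_dbl(seq_along(ids), function(i) {
      rmse_reduction(shp[[i]], conv_smo[[i]], smo[[i]])
    }),
    reduction_to_sharp = purrr::map_dbl(seq_along(ids), function(i) {
      rmse_reduction(smo[[i]], conv_shp[[i]], shp[[i]])
    })
  )

  ex_cfg <- extractor_config(config$preset_registry)
  tab_ori_smo <- extract_feature_table(smo, masks, ex_cfg, "ori_smo")
  tab_ori_shp <- extract_feature_table(shp, masks, ex_cfg, "ori_shp")
  tab_conv_smo <- extract_feature_table(conv_smo, masks, ex_cfg, "conv_smo")
  tab_conv_shp <- extract_feature_table(conv_shp, masks, ex_cfg, "conv_shp")

  reg <- ex_cfg$registry
  ccc_reports <- list(
    ori_smo_vs_ori_shp = ccc_table(tab_ori_smo, tab_ori_shp, reg),
    ori_smo_vs_conv_smo = ccc_table(tab_ori_smo, tab_conv_smo, reg),
    ori_shp_vs_conv_shp = ccc_table(tab_ori_shp, tab_conv_shp, reg)
  )
  ccc_summary <- purrr::map(ccc_reports, glance) |> dplyr::bind_rows()
  ccc_summary$fraction_high <- purrr::map_dbl(
    ccc_reports, fraction_high, threshold = config$ccc_threshold)

  base <- tidy(ccc_reports$ori_smo_vs_ori_shp)
  ccc_tests <- purrr::map(
    c("ori_smo_vs_conv_smo", "ori_shp_vs_conv_shp"), function(nm) {
      other <- tidy(ccc_reports[[nm]])
      keep <- is.finite(base$ccc) & is.finite(other$ccc)
      res <- wilcoxon_signed_rank(other$ccc[keep], base$ccc[keep])
      tibble(comparison = paste("ori_smo_vs_ori_shp vs", nm),
             W = res$W, Z = res$Z, p.value = res$p, n_features = sum(keep),
             mode = res$mode)
    }) |> dplyr::bind_rows()

  ccc_grouped <- purrr::imap(ccc_reports, function(rep, nm) {
    g <- grouped_ccc(rep)
    g$comparison <- nm
    g
  }) |> dplyr::bind_rows()

  assignment <- assign_mixed(val, derive_seed(seed, "assign"))
  mixed <- mix_feature_tables(tab_ori_smo, tab_ori_shp, tab_conv_smo,
                              tab_conv_shp, assignment)
  auc_report <- auc_distribution(mixed, cohort_labels(val),
                                 ccc_reports = ccc_reports,
                                 top_k = config$top_k)

  structure(
    list(
      config = config,
      cohort_sizes = c(development = config$dev_n, validation = config$val_n),
      converters = converters,
      rmse = rmse_tab,
      feature_tables = list(ori_smo = tab_ori_smo, ori_shp = tab_ori_shp,
                            conv_smo = tab_conv_smo, conv_shp = tab_conv_shp),
      ccc_reports = ccc_reports,
      ccc_summary = ccc_summary,
      ccc_tests = ccc_tests,
      ccc_grouped = ccc_grouped,
      assignment = assignment,
      auc_report = auc_report,
      provenance = list(seed = seed, preset = config$preset,
                        extractor_version = ex_cfg$version,
                        package_version = as.character(utils::packageVersion("radkern")))
    ),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> development n = %d, validation n = %d (seed %d)\n",
              x$cohort_sizes["development"], x$cohort_sizes["validation"],
              x$provenance$seed))
  cat(sprintf("  mean RMSE reduction: %.1f%% (to smooth), %.1f%% (to sharp)\n",
              mean(x$rmse$reduction_to_smooth),
              mean(x$rmse$reduction_to_sharp)))
  cat("  CCC summary:\n")
  for (i in seq_len(nrow(x$ccc_summary))) {
    s <- x$ccc_summary[i, ]
    cat(sprintf("    %-22s mean %.3f +/- %.3f, median %.3f, fraction > %.2f: %.3f\n",
                s$comparison, s$mean_ccc, s$sd_ccc, s$median_ccc,
                x$config$ccc_threshold, s$fraction_high))
  }
  print(x$auc_report)
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Machine-readable CSVs (per-feature CCC entries per comparison, grouped
#' CCC means, per-feature AUCs, top-feature table, per-patient RMSE
#' reductions, converter training logs) plus a `summary.json` holding the
#' scalar summaries and provenance. Output is deterministic: two runs of the
#' same config produce byte-identical files.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(dir, name), row.names = FALSE, na = "")
  }
  for (nm in names(report$ccc_reports)) {
    wcsv(tidy(report$ccc_reports[[nm]]), paste0("ccc_", nm, ".csv"))
  }
  wcsv(report$ccc_summary, "ccc_summary.csv")
  wcsv(report$ccc_tests, "ccc_signed_rank_tests.csv")
  wcsv(report$ccc_grouped, "ccc_grouped_means.csv")
  wcsv(report$auc_report$aucs, "auc_per_feature.csv")
  wcsv(report$auc_report$summary, "auc_summary.csv")
  wcsv(report$auc_report$comparisons, "auc_signed_rank_tests.csv")
  wcsv(report$auc_report$top_features, "top_features.csv")
  wcsv(report$rmse, "rmse_reduction.csv")
  wcsv(as_tibble(unclass(report$assignment)), "mixed_assignment.csv")
  for (nm in names(report$feature_tables)) {
    write_feature_table(report$feature_tables[[nm]],
                        file.path(dir, paste0("features_", nm, ".csv")))
  }
  for (nm in names(report$converters)) {
    wcsv(tidy(report$converters[[nm]]), paste0("training_log_", nm, ".csv"))
  }
  jsonlite::write_json(
    list(
      provenance = report$provenance,
      cohort_sizes = as.list(report$cohort_sizes),
      rmse_reduction_mean = list(
        to_smooth = mean(report$rmse$reduction_to_smooth),
        to_sharp = mean(report$rmse$reduction_to_sharp)
      ),
      ccc = purrr::transpose(report$ccc_summary),
      ccc_signed_rank = purrr::transpose(report$ccc_tests),
      auc_summary = purrr::transpose(report$auc_report$summary),
      auc_signed_rank = purrr::transpose(report$auc_report$comparisons)
    ),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}
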