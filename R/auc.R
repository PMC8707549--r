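#' Randomly assign patients to a kernel arm (mixed-cohort design)
#'
#' Mimics a retrospective multi-center collection in which each patient's
#' image comes from one reconstruction kernel: a uniform random permutation
#' splits the cohort into a smooth arm and a sharp arm differing in size by
#' at most one (the smooth arm gets floor(n/2)).
#'
#' @param cohort A `kernel_cohort`.
#' @param seed Integer seed; the assignment is reproducible from it.
#' @return A `mixed_assignment` tibble (`patient_id`, `arm`).
#' @export
assign_mixed <- function(cohort, seed) {
  stopifnot(inherits(cohort, "kernel_cohort"))
  ids <- vapply(cohort$records, `[[`, character(1), "id")
  n <- length(ids)
  if (n < 2) abort("cohort needs at least 2 patients")
  n_smooth <- floor(n / 2)
  perm <- with_seed(derive_seed(seed, "mixed"), sample(n))
  arm <- rep("sharp", n)
  arm[perm[seq_len(n_smooth)]] <- "smooth"
  out <- tibble(patient_id = ids, arm = arm)
  structure(out, class = c("mixed_assignment", class(out)), seed = seed)
}

#' Assemble the three mixed-kernel feature tables from per-setting tables
#'
#' `ori_mix` takes each patient's assigned-arm original rendering;
#' `conv_mix_smo` keeps the smooth arm and replaces the sharp arm by its
#' sharp-to-smooth conversions; `conv_mix_shp` keeps the sharp arm and
#' replaces the smooth arm by its smooth-to-sharp conversions.
#'
#' @param ori_smo,ori_shp,conv_smo,conv_shp Feature tables for the four
#'   kernel settings, identical patients and columns.
#' @param assignment A [assign_mixed()] result.
#' @return A `grouped_feature_tables` list with elements `ori_mix`,
#'   `conv_mix_smo`, `conv_mix_shp`.
#' @export
mix_feature_tables <- function(ori_smo, ori_shp, conv_smo, conv_shp,
                               assignment) {
  stopifnot(inherits(assignment, "mixed_assignment"))
  tabs <- list(ori_smo = ori_smo, ori_shp = ori_shp,
               conv_smo = conv_smo, conv_shp = conv_shp)
  cols <- feature_columns(ori_smo)
  for (nm in names(tabs)) {
    if (!identical(feature_columns(tabs[[nm]]), cols)) {
      abort(sprintf("feature columns of %s differ from ori_smo", nm))
    }
    if (!setequal(tabs[[nm]]$patient_id, assignment$patient_id)) {
      abort(sprintf("patients of %s do not match the assignment", nm))
    }
    tabs[[nm]] <- tabs[[nm]][match(assignment$patient_id,
                                   tabs[[nm]]$patient_id), ]
  }
  smo_arm <- assignment$arm == "smooth"
  pick <- function(smooth_tab, sharp_tab, setting) {
    out <- smooth_tab
    out[!smo_arm, ] <- sharp_tab[!smo_arm, ]
    attr(out, "setting") <- setting
    out
  }
  structure(
    list(
      ori_mix = pick(tabs$ori_smo, tabs$ori_shp, "ori_mix"),
      conv_mix_smo = pick(tabs$ori_smo, tabs$conv_smo, "conv_mix_smo"),
      conv_mix_shp = pick(tabs$conv_shp, tabs$ori_shp, "conv_mix_shp")
    ),
    class = "grouped_feature_tables",
    assignment = assignment
  )
}

#' Build the mixed-group feature tables from a cohort and trained converters
#'
#' Converts each patient's off-arm rendering with the appropriate converter,
#' extracts features identically for the original mixed group and the two
#' converted mixed groups, and returns the three aligned tables.
#'
#' @param cohort A `kernel_cohort`.
#' @param assignment A [assign_mixed()] result for this cohort.
#' @param to_smooth,to_sharp Trained `kernel_converter`s for the two
#'   directions.
#' @param config An [extractor_config()].
#' @return A `grouped_feature_tables` list (see [mix_feature_tables()]).
#' @export
build_groups <- function(cohort, assignment, to_smooth, to_sharp,
                         config = extractor_config()) {
  stopifnot(inherits(cohort, "kernel_cohort"),
            inherits(assignment, "mixed_assignment"),
            inherits(to_smooth, "kernel_converter"),
            inherits(to_sharp, "kernel_converter"))
  if (to_smooth$config$direction != "to_smooth") {
    abort("to_smooth converter has the wrong direction")
  }
  if (to_sharp$config$direction != "to_sharp") {
    abort("to_sharp converter has the wrong direction")
  }
  ids <- vapply(cohort$records, `[[`, character(1), "id")
  if (!setequal(ids, assignment$patient_id)) {
    abort("assignment does not cover the cohort")
  }
  masks <- purrr::map(cohort$records, "mask")
  names(masks) <- ids
  smo <- purrr::map(cohort$records, "smooth_image")
  shp <- purrr::map(cohort$records, "sharp_image")
  names(smo) <- names(shp) <- ids
  conv_smo <- purrr::map(shp, ~convert_volume(to_smooth, .x))
  conv_shp <- purrr::map(smo, ~convert_volume(to_sharp, .x))
  mix_feature_tables(
    extract_feature_table(smo, masks, config, "ori_smo"),
    extract_feature_table(shp, masks, config, "ori_shp"),
    extract_feature_table(conv_smo, masks, config, "conv_smo"),
    extract_feature_table(conv_shp, masks, config, "conv_shp"),
    assignment
  )
}

#' Univariate AUC of one feature as a classifier score
#'
#' Rank-based AUC equal to the normalized Mann-Whitney U statistic with
#' midrank tie handling: `U / (n1 * n0)`. With `orientation_correct = TRUE`
#' (the default) the AUC is mapped to `max(A, 1 - A)`, making the screen
#' direction-agnostic as in univariate biomarker panels.
#'
#' @param values Per-patient feature values.
#' @param labels Binary labels (0/1) aligned with `values`.
#' @param orientation_correct Apply `max(A, 1 - A)`.
#' @return AUC in `[0, 1]` (in `[0.5, 1]` after orientation correction).
#' @examples
#' univariate_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))        # 1
#' univariate_auc(c(1, 3, 2, 4), c(0, 0, 1, 1), FALSE) # 0.75
#' @export
univariate_auc <- function(values, labels, orientation_correct = TRUE) {
  if (length(values) != length(labels)) abort("values and labels must align")
  if (length(values) < 4) abort("need at least 4 patients")
  if (!all(labels %in% c(0, 1))) abort("labels must be binary 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(values)
  u <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  a <- u / (n1 * n0)
  if (orientation_correct) max(a, 1 - a) else a
}

group_auc_vector <- function(tab, labels, orientation_correct = TRUE) {
  feats <- feature_columns(tab)
  labs <- labels[tab$patient_id]
  vapply(feats, function(f) {
    x <- tab[[f]]
    keep <- is.finite(x)
    if (sum(keep) < 4 || length(unique(labs[keep])) < 2) return(NA_real_)
    univariate_auc(x[keep], labs[keep], orientation_correct)
  }, double(1))
}

#' Univariate AUC screen across the mixed-kernel groups
#'
#' Computes each feature's orientation-corrected AUC in each mixed group,
#' summarizes every group by median and median absolute deviation, compares
#' each converted group's AUCs against the original mixed group with the
#' two-tailed paired Wilcoxon signed-rank test across features (Z and p), and
#' tabulates the top-k features by converted-to-smooth AUC (joined with their
#' CCC comparisons when reports are supplied).
#'
#' @param tables A `grouped_feature_tables` (see [build_groups()]).
#' @param labels Named binary vector (names = patient ids), e.g.
#'   [cohort_labels()].
#' @param ccc_reports Optional named list of `ccc_report`s to join into the
#'   top-k table (names become column prefixes).
#' @param top_k Number of top features to tabulate (default 3).
#' @param orientation_correct Apply `max(A, 1 - A)` per feature.
#' @return An `auc_report` with elements `aucs` (per-feature tibble),
#'   `summary` (median +/- MAD per group), `comparisons` (signed-rank vs
#'   ori_mix) and `top_features`.
#' @export
auc_distribution <- function(tables, labels, ccc_reports = NULL, top_k = 3,
                             orientation_correct = TRUE) {
  stopifnot(inherits(tables, "grouped_feature_tables"))
  ids <- tables$ori_mix$patient_id
  if (is.null(names(labels)) || !all(ids %in% names(labels))) {
    abort("labels must be a named vector covering every patient id")
  }
  groups <- c("ori_mix", "conv_mix_smo", "conv_mix_shp")
  aucs <- tibble(feature = feature_columns(tables$ori_mix))
  for (g in groups) {
    aucs[[g]] <- unname(group_auc_vector(tables[[g]], labels,
                                         orientation_correct))
  }
  summary <- purrr::map(groups, function(g) {
    v <- aucs[[g]][is.finite(aucs[[g]])]
    tibble(group = g, n_defined = length(v),
           median_auc = median(v),
           mad_auc = mad(v, constant = 1))
  }) |> dplyr::bind_rows()
  comparisons <- purrr::map(c("conv_mix_smo", "conv_mix_shp"), function(g) {
    keep <- is.finite(aucs[[g]]) & is.finite(aucs$ori_mix)
    n_nonzero <- sum(aucs[[g]][keep] != aucs$ori_mix[keep])
    if (n_nonzero > 0 && n_nonzero < 5) {
      # too few non-tied features for the signed-rank test
      return(tibble(group = g, W = NA_real_, Z = NA_real_, p.value = NA_real_,
                    n_features = sum(keep), mode = "insufficient",
                    no_difference = FALSE))
    }
    res <- wilcoxon_signed_rank(aucs[[g]][keep], aucs$ori_mix[keep])
    tibble(group = g, W = res$W, Z = res$Z, p.value = res$p,
           n_features = sum(keep), mode = res$mode,
           no_difference = isTRUE(res$no_difference))
  }) |> dplyr::bind_rows()
  top <- aucs |>
    dplyr::filter(is.finite(.data$conv_mix_smo)) |>
    dplyr::arrange(dplyr::desc(.data$conv_mix_smo)) |>
    dplyr::slice_head(n = top_k)
  if (!is.null(ccc_reports)) {
    for (nm in names(ccc_reports)) {
      rep_tab <- tidy(ccc_reports[[nm]])[, c("feature", "ccc")]
      names(rep_tab)[2] <- paste0("ccc_", nm)
      top <- dplyr::left_join(top, rep_tab, by = "feature")
    }
  }
  structure(
    list(aucs = aucs, summary = summary, comparisons = comparisons,
         top_features = top),
    class = "auc_report"
  )
}

#' @export
print.auc_report <- function(x, ...) {
  cat("<auc_report> univariate AUC by mixed group\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-13s median %.3f +/- %.3f MAD (n = %d features)\n",
                x$summary$group[i], x$summary$median_auc[i],
                x$summary$mad_auc[i], x$summary$n_defined[i]))
  }
  for (i in seq_len(nrow(x$comparisons))) {
    cat(sprintf("  %s vs ori_mix: Z = %.2f, p = %.3g\n",
                x$comparisons$group[i], x$comparisons$Z[i],
                x$comparisons$p.value[i]))
  }
  invisible(x)
}

#' @rdname tidy.ccc_report
#' @export
tidy.auc_report <- function(x, ...) {
  tidyr::pivot_longer(x$aucs, -"feature", names_to = "group",
                      values_to = "auc")
}

#' @rdname tidy.ccc_report
#' @export
glance.auc_report <- function(x, ...) {
  wide <- x$summary |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("median_auc", "mad_auc", "n_defined"))
  comp <- x$comparisons
  for (i in seq_len(nrow(comp))) {
    wide[[paste0("Z_", comp$group[i])]] <- comp$Z[i]
    wide[[paste0("p_", comp$group[i])]] <- comp$p.value[i]
  }
  wide
}

#' Plot the AUC distributions of the mixed groups
#'
#' Boxplot of per-feature univariate AUCs per mixed group.
#'
#' @param object An `auc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.auc_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$auc), ]
  df$group <- factor(df$group, levels = c("ori_mix", "conv_mix_smo",
                                          "conv_mix_shp"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$auc)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "univariate AUC") +
    ggplot2::theme_minimal()
}
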