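#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with population
#' (1/n) moments, following Lin's original estimator. Unlike Pearson
#' correlation, the CCC penalizes location and scale shifts, so it measures
#' agreement rather than mere linear association.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 3), finite values.
#' @return The CCC in `[-1, 1]`, or `NA` (undefined flag) when the
#'   denominator is zero (both vectors constant and equal).
#' @examples
#' ccc(1:10, 1:10)       # 1: perfect concordance
#' ccc(1:10, 1:10 + 2)   # < 1: location shift is penalized
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("values must be finite")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) return(NA_real_)
  2 * sxy / denom
}

#' Per-feature CCC between two kernel settings
#'
#' Computes one CCC per shared feature column between two feature tables
#' (patients aligned by id). Pairs where either table has an undefined (NA)
#' value are dropped per feature, with the remaining pair count recorded;
#' features left with fewer than 3 pairs, or with a degenerate denominator,
#' carry the undefined flag and are excluded from summaries.
#'
#' @param a,b Feature tables (see [extract_feature_table()]) with identical
#'   patient sets and feature columns.
#' @param registry Optional registry tibble used to attach family/group
#'   labels to the entries.
#' @return A `ccc_report`: tibble of entries (`feature`, `ccc`, `n`) with the
#'   comparison label in attributes; `glance()` gives mean, sd, median and
#'   the fraction above threshold.
#' @export
ccc_table <- function(a, b, registry = NULL) {
  fa <- feature_columns(a); fb <- feature_columns(b)
  shared <- intersect(fa, fb)
  if (length(shared) == 0) abort("the two tables share no feature columns")
  if (!setequal(a$patient_id, b$patient_id)) {
    abort("the two tables must cover the same patients")
  }
  b <- b[match(a$patient_id, b$patient_id), ]
  entries <- purrr::map(shared, function(f) {
    x <- a[[f]]; y <- b[[f]]
    keep <- is.finite(x) & is.finite(y)
    n <- sum(keep)
    val <- if (n >= 3) ccc(x[keep], y[keep]) else NA_real_
    tibble(feature = f, ccc = val, n = n)
  }) |> dplyr::bind_rows()
  if (!is.null(registry)) {
    entries <- dplyr::left_join(
      entries, registry[, c("feature", "family", "group")], by = "feature")
  }
  structure(entries,
            class = c("ccc_report", class(entries)),
            comparison = paste(feature_table_setting(a), "vs",
                               feature_table_setting(b)))
}

#' @export
print.ccc_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ccc_report> %s: %d features (%d defined)\n",
              attr(x, "comparison"), nrow(x), g$n_defined))
  cat(sprintf("  CCC mean %.3f +/- %.3f, median %.3f, fraction > 0.85: %.3f\n",
              g$mean_ccc, g$sd_ccc, g$median_ccc, g$fraction_high))
  invisible(x)
}

#' Tidy and summarize analysis objects
#'
#' `tidy()` returns the per-item table of a fitted or computed object
#' (per-feature CCC entries, per-epoch converter losses, per-feature AUCs);
#' `glance()` returns its one-row summary.
#'
#' @param x A `ccc_report`, `kernel_converter`, `auc_report` or
#'   `signed_rank_test` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ccc_report <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.ccc_report
#' @export
glance.ccc_report <- function(x, ...) {
  v <- x$ccc[is.finite(x$ccc)]
  tibble(
    comparison = attr(x, "comparison"),
    n_features = nrow(x),
    n_defined = length(v),
    mean_ccc = mean(v),
    sd_ccc = sd(v),
    median_ccc = median(v),
    fraction_high = fraction_high(x)
  )
}

#' Fraction of features with CCC above a threshold
#'
#' Strict inequality; the denominator counts only defined entries.
#'
#' @param report A `ccc_report`.
#' @param threshold Reproducibility threshold, default 0.85.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_high <- function(report, threshold = 0.85) {
  stopifnot(inherits(report, "ccc_report"))
  v <- report$ccc[is.finite(report$ccc)]
  if (length(v) == 0) abort("all CCC entries are undefined")
  mean(v > threshold)
}

#' Group-averaged CCC (heatmap analog)
#'
#' Mean of defined CCC entries per feature group, ordered by group id — the
#' tabular analog of a grouped reproducibility heatmap row.
#'
#' @param report A `ccc_report`.
#' @param registry Registry tibble providing the feature-to-group mapping
#'   (unnecessary when the report already carries groups).
#' @return Tibble with `group`, `n_features`, `n_defined`, `mean_ccc`.
#' @export
grouped_ccc <- function(report, registry = NULL) {
  stopifnot(inherits(report, "ccc_report"))
  entries <- as_tibble(unclass(report))
  if (!"group" %in% names(entries) || all(is.na(entries$group))) {
    if (is.null(registry)) abort("supply a registry with feature groups")
    entries <- dplyr::left_join(
      entries[, c("feature", "ccc", "n")],
      registry[, c("feature", "group")], by = "feature")
  }
  miss <- entries$feature[is.na(entries$group)]
  if (length(miss)) {
    abort(sprintf("ungrouped feature(s): %s", paste(miss, collapse = ", ")))
  }
  entries |>
    dplyr::group_by(group) |>
    dplyr::summarise(
      n_features = dplyr::n(),
      n_defined = sum(is.finite(ccc)),
      mean_ccc = if (any(is.finite(ccc))) mean(ccc[is.finite(ccc)]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(group)
}

#' Plot a CCC report
#'
#' Dot plot of per-feature CCC ordered by group (heatmap analog), with the
#' reproducibility threshold marked.
#'
#' @param object A `ccc_report`.
#' @param threshold Threshold line, default 0.85.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ccc_report <- function(object, threshold = 0.85, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$ccc), ]
  df$feature <- factor(df$feature, levels = df$feature[order(df$group %||% 1, df$feature)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ccc, y = .data$feature)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Lin's CCC", y = NULL, title = attr(object, "comparison")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
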