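#' Two-tailed Wilcoxon signed-rank test
#'
#' Paired test of the null that the median difference is zero. Differences of
#' exactly zero are discarded (Wilcoxon's rule; the count is reported),
#' absolute differences receive midranks, and W is the sum of ranks of
#' positive differences. In exact mode the null distribution of W is obtained
#' over all 2^n sign patterns (computed by a dynamic-programming convolution
#' over the doubled midranks, which is identical to full enumeration);
#' `auto` uses it for n <= 25 without ties, otherwise the normal
#' approximation with tie correction and a 0.5 continuity correction.
#'
#' @param x,y Paired numeric vectors of equal length; at least 5 non-zero
#'   differences are required.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return A `signed_rank_test` with fields `W`, `Z` (normal-approximation
#'   statistic, sign of W minus its null mean), `p` (two-tailed),
#'   `n_effective`, `n_zeros`, `mode`. When all differences are zero the
#'   result is flagged `no_difference = TRUE` with p = 1.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1))
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) abort("x and y must have equal length")
  d <- x - y
  if (!all(is.finite(d))) abort("values must be finite")
  n_zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(
      list(W = 0, Z = 0, p = 1, n_effective = 0L, n_zeros = n_zeros,
           mode = "degenerate", no_difference = TRUE),
      class = "signed_rank_test"
    ))
  }
  if (n < 5) abort("need at least 5 non-zero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = n <= 25 && !has_ties
  )
  if (use_exact && n > 25) {
    abort("exact mode is limited to 25 non-zero differences")
  }

  mu <- n * (n + 1) / 4
  tie_counts <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_counts^3 - tie_counts) / 48
  if (sigma2 > 0) {
    cc <- sign(W - mu) * 0.5
    Z <- (W - mu - cc) / sqrt(sigma2)
  } else {
    Z <- 0
  }

  if (use_exact) {
    # Exact null distribution of 2W by convolution over doubled midranks
    # (identical to enumerating all 2^n sign patterns).
    r2 <- as.integer(round(2 * r))
    probs <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), probs[seq_len(length(probs) - ri)])
      probs <- (probs + shifted) / 2
    }
    w2 <- as.integer(round(2 * W))
    lower <- sum(probs[seq_len(w2 + 1L)])            # P(2W <= w2)
    upper <- sum(probs[(w2 + 1L):length(probs)])     # P(2W >= w2)
    p <- min(1, 2 * min(lower, upper))
    mode_used <- "exact"
  } else {
    p <- if (sigma2 > 0) min(1, 2 * pnorm(-abs(Z))) else 1
    mode_used <- "approx"
  }
  structure(
    list(W = W, Z = Z, p = p, n_effective = n, n_zeros = n_zeros,
         mode = mode_used, no_difference = FALSE),
    class = "signed_rank_test"
  )
}

#' @export
print.signed_rank_test <- function(x, ...) {
  if (isTRUE(x$no_difference)) {
    cat("<signed_rank_test> all paired differences are zero: no difference (p = 1)\n")
  } else {
    cat(sprintf("<signed_rank_test> W = %g, Z = %.3f, p = %.4g (%s mode, n = %d, %d zeros dropped)\n",
                x$W, x$Z, x$p, x$mode, x$n_effective, x$n_zeros))
  }
  invisible(x)
}

#' @rdname tidy.ccc_report
#' @export
tidy.signed_rank_test <- function(x, ...) {
  tibble(W = x$W, Z = x$Z, p.value = x$p, n_effective = x$n_effective,
         n_zeros = x$n_zeros, mode = x$mode,
         no_difference = isTRUE(x$no_difference))
}

#' One-way ANOVA across groups
#'
#' Standard fixed-effects F test for equality of group means, via
#' `stats::oneway.test` with pooled variance. Degenerate inputs (zero pooled
#' variance) are flagged: p = 1 when all group means are equal, p = 0
#' otherwise.
#'
#' @param groups List of numeric vectors (each n >= 2).
#' @return A `group_comparison` with `statistic` (F), `df`, `p`,
#'   `group_sizes`, `test`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) abort("each group needs at least 2 values")
  vals <- unlist(groups)
  if (!all(is.finite(vals))) abort("values must be finite")
  g <- factor(rep(seq_along(groups), sizes))
  pooled_var <- sum(vapply(groups, function(x) sum((x - mean(x))^2), double(1))) /
    (length(vals) - length(groups))
  means <- vapply(groups, mean, double(1))
  if (pooled_var == 0) {
    equal <- max(means) - min(means) == 0
    return(structure(
      list(statistic = if (equal) 0 else Inf,
           df = c(length(groups) - 1, length(vals) - length(groups)),
           p = if (equal) 1 else 0, group_sizes = sizes,
           test = "oneway_anova", degenerate = TRUE),
      class = "group_comparison"
    ))
  }
  ft <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  structure(
    list(statistic = unname(ft$statistic), df = unname(ft$parameter),
         p = ft$p.value, group_sizes = sizes, test = "oneway_anova",
         degenerate = FALSE),
    class = "group_comparison"
  )
}

#' Two-sample t test
#'
#' Wrapper over `stats::t.test` (two-tailed) with the same degenerate-input
#' flagging as [anova_oneway()].
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param equal_var Pooled-variance (Student) test when TRUE, Welch otherwise.
#' @return A `group_comparison` with `statistic` (t), `df`, `p`.
#' @export
t_test_two_sample <- function(a, b, equal_var = TRUE) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 values")
  if (!all(is.finite(c(a, b)))) abort("values must be finite")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    equal <- mean(a) == mean(b)
    return(structure(
      list(statistic = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
           df = length(a) + length(b) - 2,
           p = if (equal) 1 else 0,
           group_sizes = c(length(a), length(b)),
           test = if (equal_var) "t_student" else "t_welch",
           degenerate = TRUE),
      class = "group_comparison"
    ))
  }
  tt <- stats::t.test(a, b, var.equal = equal_var)
  structure(
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, group_sizes = c(length(a), length(b)),
         test = if (equal_var) "t_student" else "t_welch",
         degenerate = FALSE),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison %s> statistic = %.4g, df = %s, p = %.4g%s\n",
              x$test, x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p, if (isTRUE(x$degenerate)) " (degenerate input)" else ""))
  invisible(x)
}
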