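#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_chr map_lgl imap
#' @importFrom stats fft rnorm runif sd median mad quantile pnorm
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Deterministic 32-bit seed derivation: every stage/record draws its own seed
# from the master seed so regeneration is order-independent.
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L)
  tags <- list(...)
  h <- as.double(master) %% 2147483647
  for (tag in tags) {
    if (is.character(tag)) {
      v <- utf8ToInt(tag)
    } else {
      v <- as.double(tag)
    }
    for (x in v) {
      # 64-bit-safe linear congruential mixing kept under 2^31 - 1
      h <- (h * 48271 + (x %% 2147483647) + 1) %% 2147483647
    }
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

assert_finite_array <- function(x, what = "volume") {
  if (!all(is.finite(x))) {
    abort(sprintf("%s contains non-finite values", what))
  }
  invisible(x)
}

assert_same_shape <- function(a, b, what = c("a", "b")) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (length(da) != length(db) || any(da != db)) {
    abort(sprintf(
      "shape mismatch: %s is %s but %s is %s",
      what[1], paste(da, collapse = "x"), what[2], paste(db, collapse = "x")
    ))
  }
  invisible(TRUE)
}

# Shannon entropy in bits of a count/probability vector; zero cells dropped.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  p <- p / sum(p)
  -sum(p * log2(p))
}
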