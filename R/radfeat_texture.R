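# Texture-matrix feature families (GLCM, GLRLM, GLSZM, NGTDM) computed on a
# gray-level-quantized ROI. Throughout, an undefined feature is returned as
# NA_real_ (the "undefined" flag): downstream reproducibility summaries drop
# flagged values explicitly instead of treating them as zeros.

mask_values <- function(mask) {
  if (inherits(mask, "lesion_mask")) mask$values else mask
}

# The 13 unique 3D unit offsets (one per +/- direction pair).
offsets_13 <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

# All 26 neighbor offsets.
offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

#' Quantize a lesion ROI to discrete gray levels
#'
#' Equal-width bins between the in-mask minimum and maximum; a constant ROI
#' maps every voxel to level 1. The result covers the mask's bounding box
#' with level 0 outside the mask.
#'
#' @param volume A `ct_volume` or 3D array.
#' @param mask A `lesion_mask` or logical array of the same shape.
#' @param n_levels Number of gray levels (>= 2).
#' @return A `quantized_roi` with fields `levels` (integer array over the
#'   bounding box, 0 outside the mask), `n_levels` and `bin_edges`.
#' @export
quantize_roi <- function(volume, mask, n_levels = 32L) {
  vals <- volume_values(volume)
  mk <- mask_values(mask)
  assert_same_shape(vals, mk, c("volume", "mask"))
  if (!any(mk)) abort("mask is empty")
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) abort("n_levels must be >= 2")
  idx <- which(mk, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  sub_m <- mk[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_v <- vals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub_m) <- dim(sub_v) <- hi - lo + 1L
  x <- sub_v[sub_m]
  mn <- min(x); mx <- max(x)
  if (mx > mn) {
    edges <- seq(mn, mx, length.out = n_levels + 1L)
    lev <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  } else {
    edges <- seq(mn - 0.5, mn + 0.5, length.out = n_levels + 1L)
    lev <- rep(1L, length(x))
  }
  levels <- array(0L, dim = dim(sub_m))
  levels[sub_m] <- as.integer(lev)
  structure(
    list(levels = levels, n_levels = n_levels, bin_edges = edges,
         bbox_origin = lo),
    class = "quantized_roi"
  )
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %s bounding box, %d voxels in mask, %d levels\n",
              paste(dim(x$levels), collapse = "x"), sum(x$levels > 0),
              x$n_levels))
  invisible(x)
}

# Pad the level array with a 1-voxel zero border so linear-index stepping can
# never wrap around array edges.
pad_levels <- function(L) {
  d <- dim(L)
  P <- array(0L, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- L
  P
}

lin_offset <- function(off, dp) {
  off[1] + off[2] * dp[1] + off[3] * dp[1] * dp[2]
}

# Pooled symmetric co-occurrence matrix over the 13 unit offsets, restricted
# to voxel pairs that are both inside the mask.
glcm_matrix <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  P <- pad_levels(q$levels)
  dp <- dim(P)
  K <- q$n_levels
  V <- which(P > 0L)
  M <- matrix(0, K, K)
  for (r in seq_len(nrow(offsets_13()))) {
    off <- lin_offset(offsets_13()[r, ], dp)
    nb <- P[V + off]
    keep <- nb > 0L
    if (!any(keep)) next
    a <- P[V][keep]; b <- nb[keep]
    # symmetric accumulation: count each unordered pair in both orders
    cnt <- tabulate(c((a - 1L) * K + b, (b - 1L) * K + a), nbins = K * K)
    M <- M + matrix(cnt, K, K)
  }
  M
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Co-occurrence counts are accumulated symmetrically over the 13 unique 3D
#' unit offsets, over voxel pairs fully inside the mask, pooled into a single
#' matrix and normalized to probabilities. Entropies are in bits.
#'
#' @param q A [quantize_roi()] result.
#' @return Named numeric vector: `GLCM_Entropy`, `GLCM_Diff_Entropy`,
#'   `GLCM_Sum_Entropy`, `GLCM_Contrast`, `GLCM_Homogeneity`, `GLCM_Energy`,
#'   `GLCM_Correlation`. Undefined values (no valid voxel pair, or zero
#'   marginal variance for the correlation) are `NA`.
#' @export
glcm_features <- function(q) {
  M <- glcm_matrix(q)
  tot <- sum(M)
  out <- c(GLCM_Entropy = NA_real_, GLCM_Diff_Entropy = NA_real_,
           GLCM_Sum_Entropy = NA_real_, GLCM_Contrast = NA_real_,
           GLCM_Homogeneity = NA_real_, GLCM_Energy = NA_real_,
           GLCM_Correlation = NA_real_)
  if (tot < 1) return(out)
  p <- M / tot
  K <- nrow(p)
  i <- row(p); j <- col(p)
  out["GLCM_Entropy"] <- shannon_entropy(p)
  pd <- vapply(0:(K - 1), function(k) sum(p[abs(i - j) == k]), double(1))
  out["GLCM_Diff_Entropy"] <- shannon_entropy(pd)
  ps <- vapply(2:(2 * K), function(k) sum(p[(i + j) == k]), double(1))
  out["GLCM_Sum_Entropy"] <- shannon_entropy(ps)
  out["GLCM_Contrast"] <- sum(p * (i - j)^2)
  out["GLCM_Homogeneity"] <- sum(p / (1 + abs(i - j)))
  out["GLCM_Energy"] <- sum(p^2)
  px <- rowSums(p)
  mu <- sum(seq_len(K) * px)
  sigma2 <- sum((seq_len(K) - mu)^2 * px)
  if (sigma2 > 0) {
    out["GLCM_Correlation"] <- (sum(p * i * j) - mu^2) / sigma2
  }
  out
}

# Run-length tallies for one direction: returns per-run (level, length).
glrlm_runs <- function(P, dp, off) {
  V <- which(P > 0L)
  loff <- lin_offset(off, dp)
  starts <- V[P[V - loff] != P[V]]
  lev <- P[starts]
  len <- integer(length(starts))
  for (s in seq_along(starts)) {
    v <- starts[s]
    l <- 1L
    nxt <- v + loff
    while (P[nxt] == lev[s]) {
      l <- l + 1L
      nxt <- nxt + loff
    }
    len[s] <- l
  }
  list(level = lev, length = len)
}

#' Gray-level run-length (GLRLM) features
#'
#' Runs are maximal same-level voxel sequences along a direction, confined to
#' the mask. Features are computed per direction and averaged over the
#' requested directions (default: all 13 unique 3D unit offsets).
#'
#' @param q A [quantize_roi()] result.
#' @param directions Integer matrix of direction offsets (rows), or `NULL`
#'   for the standard 13.
#' @return Named numeric vector: `Run_SPE` (short-run emphasis), `Run_LRE`
#'   (long-run emphasis), `Run_PP` (run percentage), `Run_GLN` (gray-level
#'   nonuniformity), `Run_RLN` (run-length nonuniformity).
#' @export
glrlm_features <- function(q, directions = NULL) {
  stopifnot(inherits(q, "quantized_roi"))
  dirs <- directions %||% offsets_13()
  if (is.null(dim(dirs))) dirs <- matrix(dirs, nrow = 1)
  P <- pad_levels(q$levels)
  dp <- dim(P)
  np <- sum(q$levels > 0L)
  per_dir <- matrix(NA_real_, nrow(dirs), 5)
  colnames(per_dir) <- c("Run_SPE", "Run_LRE", "Run_PP", "Run_GLN", "Run_RLN")
  for (r in seq_len(nrow(dirs))) {
    runs <- glrlm_runs(P, dp, dirs[r, ])
    nr <- length(runs$length)
    if (nr == 0) next
    per_dir[r, "Run_SPE"] <- mean(1 / runs$length^2)
    per_dir[r, "Run_LRE"] <- mean(runs$length^2)
    per_dir[r, "Run_PP"] <- nr / np
    per_dir[r, "Run_GLN"] <- sum(tabulate(runs$level, q$n_levels)^2) / nr
    per_dir[r, "Run_RLN"] <- sum(tabulate(runs$length)^2) / nr
  }
  colMeans(per_dir)
}

# 26-connected same-level zones: returns per-zone (level, size).
glszm_zones <- function(q) {
  P <- pad_levels(q$levels)
  dp <- dim(P)
  offs <- apply(offsets_26(), 1, lin_offset, dp = dp)
  V <- which(P > 0L)
  visited <- logical(length(P))
  zl <- integer(0); zs <- integer(0)
  for (v in V) {
    if (visited[v]) next
    lev <- P[v]
    visited[v] <- TRUE
    frontier <- v
    size <- 1L
    while (length(frontier) > 0) {
      cand <- unique(as.vector(outer(frontier, offs, `+`)))
      cand <- cand[P[cand] == lev & !visited[cand]]
      visited[cand] <- TRUE
      size <- size + length(cand)
      frontier <- cand
    }
    zl <- c(zl, lev); zs <- c(zs, size)
  }
  list(level = zl, size = zs)
}

#' Gray-level size-zone (GLSZM) features
#'
#' Zones are 26-connected components of equal gray level inside the mask.
#'
#' @param q A [quantize_roi()] result.
#' @return Named numeric vector: `SizeZone_SZE` (small-zone emphasis),
#'   `SizeZone_LZE` (large-zone emphasis), `SizeZone_ZP` (zone percentage),
#'   `SizeZone_GLN` (gray-level nonuniformity).
#' @export
glszm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  z <- glszm_zones(q)
  np <- sum(q$levels > 0L)
  nz <- length(z$size)
  if (nz == 0) {
    return(c(SizeZone_SZE = NA_real_, SizeZone_LZE = NA_real_,
             SizeZone_ZP = NA_real_, SizeZone_GLN = NA_real_))
  }
  c(
    SizeZone_SZE = mean(1 / z$size^2),
    SizeZone_LZE = mean(z$size^2),
    SizeZone_ZP = nz / np,
    SizeZone_GLN = sum(tabulate(z$level, q$n_levels)^2) / nz
  )
}

#' Neighboring gray-tone difference (NGTDM) features
#'
#' For every voxel whose full 26-neighborhood lies inside the mask, the
#' absolute difference between its level and the neighborhood mean is
#' accumulated per level (Amadasun's s_i). Coarseness is
#' `1 / (eps + sum(p_i s_i))` with `eps = 1e-12`, capped at `1e12` for the
#' degenerate all-uniform case.
#'
#' @param q A [quantize_roi()] result.
#' @return Named numeric vector: `NGTDM_Coarseness`, `NGTDM_Busyness`,
#'   `NGTDM_Contrast`, `NGTDM_Complexity`. All `NA` (undefined) when no voxel
#'   has a complete in-mask neighborhood.
#' @export
ngtdm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  eps <- 1e-12
  P <- pad_levels(q$levels)
  dp <- dim(P)
  V <- which(P > 0L)
  nbr_sum <- numeric(length(V))
  valid <- rep(TRUE, length(V))
  for (r in seq_len(nrow(offsets_26()))) {
    off <- lin_offset(offsets_26()[r, ], dp)
    nb <- P[V + off]
    valid <- valid & nb > 0L
    nbr_sum <- nbr_sum + nb
  }
  out <- c(NGTDM_Coarseness = NA_real_, NGTDM_Busyness = NA_real_,
           NGTDM_Contrast = NA_real_, NGTDM_Complexity = NA_real_)
  if (!any(valid)) return(out)
  lev <- P[V][valid]
  diffs <- abs(lev - nbr_sum[valid] / 26)
  K <- q$n_levels
  n_i <- tabulate(lev, K)
  s_i <- vapply(seq_len(K), function(k) sum(diffs[lev == k]), double(1))
  N <- sum(n_i)
  p_i <- n_i / N
  occupied <- which(p_i > 0)
  ps <- sum(p_i * s_i)
  out["NGTDM_Coarseness"] <- min(1 / (eps + ps), 1e12)
  if (length(occupied) > 1) {
    ii <- occupied[row(matrix(0, length(occupied), length(occupied)))]
    jj <- occupied[col(matrix(0, length(occupied), length(occupied)))]
    busy_den <- sum(abs(ii * p_i[ii] - jj * p_i[jj]))
    out["NGTDM_Busyness"] <- if (busy_den > 0) ps / busy_den else NA_real_
    ngp <- length(occupied)
    out["NGTDM_Contrast"] <-
      sum(p_i[ii] * p_i[jj] * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(s_i) / N
    out["NGTDM_Complexity"] <-
      sum(abs(ii - jj) * (p_i[ii] * s_i[ii] + p_i[jj] * s_i[jj]) /
            (p_i[ii] + p_i[jj])) / N
  } else {
    out["NGTDM_Busyness"] <- NA_real_
    out["NGTDM_Contrast"] <- 0
    out["NGTDM_Complexity"] <- 0
  }
  out
}
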