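# Image-domain feature families: intensity statistics, Laplacian of
# Gaussian, gradient (edge), shape, boundary sharpness (sigmoid slope), Laws
# energies and Haar-wavelet subband energies.

# Population-moment skewness (m3 / m2^1.5); 0 by convention for zero variance.
moment_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Intensity (first-order) features
#'
#' `Intensity_Skewness_3D` is the sample skewness (m3 / m2^1.5, population
#' moments) of all in-mask intensities; `Intensity_Skewness_2D` is the mean
#' of per-axial-slice skewness over slices with at least 10 in-mask voxels
#' (NA when no slice qualifies). Zero-variance skewness/kurtosis are 0 by
#' convention. `Intensity_Entropy` is the Shannon entropy (bits) of a 64-bin
#' equal-width histogram of in-mask intensities.
#'
#' @param volume A `ct_volume` or 3D array.
#' @param mask A `lesion_mask` or logical array of the same shape.
#' @return Named numeric vector of intensity features.
#' @export
intensity_features <- function(volume, mask) {
  vals <- volume_values(volume)
  mk <- mask_values(mask)
  assert_same_shape(vals, mk, c("volume", "mask"))
  if (!any(mk)) abort("mask is empty")
  x <- vals[mk]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  kurt <- if (m2 == 0) 0 else mean((x - m)^4) / m2^2 - 3
  slice_skew <- c()
  for (z in seq_len(dim(vals)[3])) {
    xm <- vals[, , z][mk[, , z]]
    if (length(xm) >= 10) slice_skew <- c(slice_skew, moment_skewness(xm))
  }
  ent <- if (max(x) > min(x)) {
    shannon_entropy(tabulate(
      findInterval(x, seq(min(x), max(x), length.out = 65),
                   rightmost.closed = TRUE, all.inside = TRUE), 64))
  } else 0
  c(
    Intensity_Mean = m,
    Intensity_Median = median(x),
    Intensity_SD = sd(x),
    Intensity_IQR = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    Intensity_Range = max(x) - min(x),
    Intensity_Energy = mean(x^2),
    Intensity_Skewness_2D = if (length(slice_skew)) mean(slice_skew) else NA_real_,
    Intensity_Skewness_3D = moment_skewness(x),
    Intensity_Kurtosis = kurt,
    Intensity_Entropy = ent,
    Intensity_P10 = unname(quantile(x, 0.10)),
    Intensity_P75 = unname(quantile(x, 0.75)),
    Intensity_P90 = unname(quantile(x, 0.90))
  )
}

# Discrete 3D LoG kernel at scale sigma (voxel units), truncated at 4*sigma,
# DC-corrected so its coefficients sum to exactly zero.
log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  ax <- (-r):r
  g1 <- exp(-ax^2 / (2 * sigma^2))
  g <- outer(outer(g1, g1), g1)
  dim(g) <- rep(2L * r + 1L, 3)
  rho2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  dim(rho2) <- dim(g)
  k <- (rho2 / sigma^4 - 3 / sigma^2) * g
  k - mean(k)
}

# "Same"-size 3D FFT convolution (zero padding).
conv3d_fft <- function(x, kern) {
  dx <- dim(x); dk <- dim(kern)
  nf <- dx + dk - 1L
  xp <- array(0, nf); xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  kp <- array(0, nf); kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
  full <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / prod(nf)
  r <- (dk - 1L) / 2L
  full[r[1] + seq_len(dx[1]), r[2] + seq_len(dx[2]), r[3] + seq_len(dx[3]),
       drop = FALSE]
}

#' Laplacian-of-Gaussian features
#'
#' The volume is convolved with a DC-corrected LoG kernel at each sigma
#' (voxel units, truncation radius 4 sigma); in-mask responses are summarized
#' by their Shannon entropy over a 64-bin equal-width histogram (0 when the
#' responses are constant — the single-bin rule) plus mean and standard
#' deviation. The parameter index `pk` in the feature name refers to the k-th
#' sigma in `sigmas`.
#'
#' For efficiency the convolution is evaluated on the mask's bounding box
#' expanded by the kernel radius; when that window runs past the volume edge
#' the outside is treated as zero.
#'
#' @param volume A `ct_volume` or 3D array.
#' @param mask A `lesion_mask` or logical array.
#' @param sigmas Positive LoG scales in voxels; default `c(1.5, 2.5)`.
#' @return Named numeric vector with `LoG_Entropy_pk`, `LoG_Mean_pk`,
#'   `LoG_SD_pk` for each sigma.
#' @export
log_features <- function(volume, mask, sigmas = c(1.5, 2.5)) {
  vals <- volume_values(volume)
  mk <- mask_values(mask)
  assert_same_shape(vals, mk, c("volume", "mask"))
  if (!any(mk)) abort("mask is empty")
  stopifnot(all(sigmas > 0))
  d <- dim(vals)
  idx <- which(mk, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  out <- c()
  for (k in seq_along(sigmas)) {
    sigma <- sigmas[k]
    r <- ceiling(4 * sigma)
    if (any(2L * r + 1L > d)) {
      abort(sprintf("sigma %.2f gives a kernel larger than the volume", sigma))
    }
    wlo <- pmax(lo - r, 1L); whi <- pmin(hi + r, d)
    sub <- vals[wlo[1]:whi[1], wlo[2]:whi[2], wlo[3]:whi[3], drop = FALSE]
    dim(sub) <- whi - wlo + 1L
    resp <- conv3d_fft(sub, log_kernel(sigma))
    sub_mk <- mk[wlo[1]:whi[1], wlo[2]:whi[2], wlo[3]:whi[3], drop = FALSE]
    dim(sub_mk) <- dim(sub)
    x <- resp[sub_mk]
    ent <- if (max(x) - min(x) > 1e-8) {
      shannon_entropy(tabulate(
        findInterval(x, seq(min(x), max(x), length.out = 65),
                     rightmost.closed = TRUE, all.inside = TRUE), 64))
    } else 0
    block <- c(ent, mean(x), sd(x))
    names(block) <- paste0(c("LoG_Entropy_p", "LoG_Mean_p", "LoG_SD_p"), k)
    out <- c(out, block)
  }
  out
}

# Per-axis derivative by central differences (one-sided at volume borders),
# in intensity per mm.
gradient_axis <- function(vals, axis, spacing) {
  d <- dim(vals)
  n <- d[axis]
  slicer <- function(i) {
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ix[[axis]] <- i
    vals[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  }
  fwd <- slicer(c(2:n, n))
  bwd <- slicer(c(1, 1:(n - 1)))
  denom <- array(2 * spacing, dim = d)
  edge <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (i in c(1L, n)) {
    ix <- edge; ix[[axis]] <- i
    denom[ix[[1]], ix[[2]], ix[[3]]] <- spacing
  }
  g <- (fwd - bwd) / denom
  dim(g) <- d
  g
}

gradient_magnitude <- function(vals, spacing) {
  g2 <- gradient_axis(vals, 1L, spacing[1])^2 +
    gradient_axis(vals, 2L, spacing[2])^2 +
    gradient_axis(vals, 3L, spacing[3])^2
  sqrt(g2)
}

#' Edge-frequency features: mean in-mask gradient magnitude
#'
#' 3D gradient by central differences (one-sided at volume borders), scaled
#' by the voxel spacing, summarized over in-mask voxels.
#'
#' @param volume A `ct_volume` or 3D array.
#' @param mask A `lesion_mask` or logical array.
#' @param spacing Voxel spacing in mm (taken from the volume when it is a
#'   `ct_volume`).
#' @return `EdgeFreq_Mean` as a single number.
#' @export
edge_freq_mean <- function(volume, mask, spacing = NULL) {
  edge_freq_features(volume, mask, spacing)[["EdgeFreq_Mean"]]
}

#' @rdname edge_freq_mean
#' @return `edge_freq_features()`: named vector `EdgeFreq_Mean`,
#'   `EdgeFreq_SD`.
#' @export
edge_freq_features <- function(volume, mask, spacing = NULL) {
  vals <- volume_values(volume)
  mk <- mask_values(mask)
  assert_same_shape(vals, mk, c("volume", "mask"))
  if (!any(mk)) abort("mask is empty")
  spacing <- spacing %||% volume_spacing(volume)
  gm <- gradient_magnitude(vals, spacing)[mk]
  c(EdgeFreq_Mean = mean(gm),
    EdgeFreq_SD = if (length(gm) > 1) sd(gm) else 0)
}

#' Shape features of a lesion mask
#'
#' Volume is voxel count times voxel volume; surface area counts exposed
#' voxel faces times face area; compactness is `36 * pi * V^2 / A^3` (1 for a
#' perfect sphere, smaller otherwise) and sphericity its cube root; the
#' maximum 3D diameter is the largest voxel-center-to-center Euclidean
#' distance between surface voxels.
#'
#' @param mask A `lesion_mask` or logical array.
#' @param spacing Voxel spacing in mm (from the mask when a `lesion_mask`).
#' @return Named numeric vector of shape features.
#' @export
shape_features <- function(mask, spacing = NULL) {
  mk <- mask_values(mask)
  if (!any(mk)) abort("mask is empty")
  spacing <- spacing %||% (if (inherits(mask, "lesion_mask")) mask$spacing else c(1, 1, 1))
  d <- dim(mk)
  vol <- sum(mk) * prod(spacing)
  shift_mask <- function(axis, by) {
    out <- array(FALSE, d)
    n <- d[axis]
    src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    dst <- src
    if (by == 1L) { src[[axis]] <- 1:(n - 1); dst[[axis]] <- 2:n }
    else { src[[axis]] <- 2:n; dst[[axis]] <- 1:(n - 1) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- mk[src[[1]], src[[2]], src[[3]]]
    out
  }
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  area <- 0
  exposed_any <- array(FALSE, d)
  for (axis in 1:3) {
    for (by in c(1L, -1L)) {
      exposed <- mk & !shift_mask(axis, by)
      area <- area + sum(exposed) * face_area[axis]
      exposed_any <- exposed_any | exposed
    }
  }
  surf <- which(exposed_any, arr.ind = TRUE)
  coords <- sweep(surf, 2L, spacing, `*`)
  max_diam <- if (nrow(coords) > 1) max(stats::dist(coords)) else 0
  compact <- 36 * pi * vol^2 / area^3
  c(
    Shape_Volume_mm3 = vol,
    Shape_SurfaceArea_mm2 = area,
    Shape_MaxDiameter3D_mm = max_diam,
    Shape_Compactness = compact,
    Shape_Sphericity = compact^(1 / 3),
    Shape_SurfaceToVolumeRatio = area / vol
  )
}

trilinear_sample <- function(vals, pts) {
  d <- dim(vals)
  x <- pmin(pmax(pts[, 1], 1), d[1])
  y <- pmin(pmax(pts[, 2], 1), d[2])
  z <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) vals[cbind(i, j, k)]
  v000 <- at(x0, y0, z0); v100 <- at(x0 + 1, y0, z0)
  v010 <- at(x0, y0 + 1, z0); v110 <- at(x0 + 1, y0 + 1, z0)
  v001 <- at(x0, y0, z0 + 1); v101 <- at(x0 + 1, y0, z0 + 1)
  v011 <- at(x0, y0 + 1, z0 + 1); v111 <- at(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# Least-squares logistic fit to one radial intensity profile. Returns the
# maximum slope b/(4s) or NA when the fit fails.
fit_sigmoid_profile <- function(t, intens) {
  if (max(intens) - min(intens) < 1e-6) return(NA_real_)
  a0 <- intens[1]
  b0 <- intens[length(intens)] - intens[1]
  t0_0 <- t[which.min(abs(intens - (a0 + b0 / 2)))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      intens ~ a + b / (1 + exp(-(t - t0) / s)),
      start = list(a = a0, b = b0, t0 = t0_0, s = 1),
      lower = c(a = -Inf, b = -Inf, t0 = min(t) - 5, s = 1e-3),
      upper = c(a = Inf, b = Inf, t0 = max(t) + 5, s = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NA_real_)
  cf <- stats::coef(fit)
  cf[["b"]] / (4 * cf[["s"]])
}

#' Tumor boundary sharpness (sigmoid slope)
#'
#' Radial intensity profiles are cast from the mask centroid along 26
#' directions, each fitted with a logistic edge model
#' `I(t) = a + b / (1 + exp(-(t - t0)/s))`; the feature is the mean maximum
#' slope `b/(4s)` over successful fits (negative when the lesion is brighter
#' than its background, since intensity falls along the outward ray).
#'
#' @param volume A `ct_volume` or 3D array.
#' @param mask A `lesion_mask` or logical array.
#' @return Mean sigmoid slope (intensity per voxel); `NA` (undefined) with
#'   fewer than 3 successful fits.
#' @export
sigmoid_slope <- function(volume, mask) {
  vals <- volume_values(volume)
  mk <- mask_values(mask)
  assert_same_shape(vals, mk, c("volume", "mask"))
  if (!any(mk)) abort("mask is empty")
  d <- dim(vals)
  idx <- which(mk, arr.ind = TRUE)
  centroid <- colMeans(idx)
  half_extent <- max(apply(idx, 2, max) - apply(idx, 2, min)) / 2
  if (half_extent < 1.5) abort("lesion too small for boundary profiles")
  t_max <- half_extent + 6
  dirs <- offsets_26()
  dirs <- dirs / sqrt(rowSums(dirs^2))
  tt <- seq(0, t_max, by = 0.5)
  slopes <- rep(NA_real_, nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    pts <- cbind(centroid[1] + tt * dirs[r, 1],
                 centroid[2] + tt * dirs[r, 2],
                 centroid[3] + tt * dirs[r, 3])
    inside <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
      pts[, 2] >= 1 & pts[, 2] <= d[2] &
      pts[, 3] >= 1 & pts[, 3] <= d[3]
    if (sum(inside) < 6) next
    prof <- trilinear_sample(vals, pts[inside, , drop = FALSE])
    slopes[r] <- fit_sigmoid_profile(tt[inside], prof)
  }
  ok <- slopes[is.finite(slopes)]
  if (length(ok) < 3) return(NA_real_)
  mean(ok)
}

laws_kernels <- function() {
  list(L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1), S5 = c(-1, 0, 2, 0, -1))
}

# Separable 1D convolution along one axis with edge-replication padding.
conv_axis_replicate <- function(x, k, axis) {
  d <- dim(x)
  r <- (length(k) - 1L) %/% 2L
  n <- d[axis]
  out <- array(0, d)
  for (m in seq_along(k)) {
    off <- m - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ix[[axis]] <- src
    out <- out + k[m] * x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  }
  dim(out) <- d
  out
}

#' Laws texture-energy features
#'
#' Separable 3D Laws masks built from the 1D kernels L5 (level), E5 (edge)
#' and S5 (spot); the feature is the mean absolute filter response over
#' in-mask voxels (edge-replication padding, so a constant volume gives
#' exactly zero for any mask containing E5 or S5).
#'
#' @param volume A `ct_volume` or 3D array.
#' @param mask A `lesion_mask` or logical array.
#' @param combos Character vector of 3-letter kernel combinations, e.g.
#'   `"L5E5E5"` applies L5 along x, E5 along y and z.
#' @return Named numeric vector `Laws_<combo>`.
#' @export
laws_features <- function(volume, mask,
                          combos = c("L5L5L5", "E5E5E5", "S5S5S5",
                                     "L5E5E5", "L5S5S5")) {
  vals <- volume_values(volume)
  mk <- mask_values(mask)
  assert_same_shape(vals, mk, c("volume", "mask"))
  if (!any(mk)) abort("mask is empty")
  kern <- laws_kernels()
  out <- numeric(length(combos))
  names(out) <- paste0("Laws_", combos)
  for (i in seq_along(combos)) {
    parts <- substring(combos[i], c(1, 3, 5), c(2, 4, 6))
    resp <- vals
    for (axis in 1:3) resp <- conv_axis_replicate(resp, kern[[parts[axis]]], axis)
    out[i] <- mean(abs(resp[mk]))
  }
  out
}

haar_step_axis <- function(x, axis) {
  d <- dim(x)
  n <- d[axis]
  ix_odd <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ix_even <- ix_odd
  ix_odd[[axis]] <- seq(1L, n - 1L, by = 2L)
  ix_even[[axis]] <- seq(2L, n, by = 2L)
  xo <- x[ix_odd[[1]], ix_odd[[2]], ix_odd[[3]], drop = FALSE]
  xe <- x[ix_even[[1]], ix_even[[2]], ix_even[[3]], drop = FALSE]
  list(L = (xo + xe) / sqrt(2), H = (xo - xe) / sqrt(2))
}

#' One-level 3D Haar wavelet subband features
#'
#' The mask's bounding box (padded by edge replication to even dimensions
#' when necessary) undergoes one level of the 3D Haar transform; each of the
#' 8 subbands is summarized by the mean absolute coefficient over the
#' downsampled mask support (blocks containing at least one mask voxel).
#'
#' @param volume A `ct_volume` or 3D array.
#' @param mask A `lesion_mask` or logical array.
#' @return Named vector `Wavelet_LLL` ... `Wavelet_HHH` (letters ordered
#'   x, y, z); all `NA` (undefined) when the bounding box is smaller than 8
#'   voxels along any axis.
#' @export
wavelet_features <- function(volume, mask) {
  vals <- volume_values(volume)
  mk <- mask_values(mask)
  assert_same_shape(vals, mk, c("volume", "mask"))
  if (!any(mk)) abort("mask is empty")
  bands <- c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")
  out <- rep(NA_real_, 8)
  names(out) <- paste0("Wavelet_", bands)
  idx <- which(mk, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  if (any(hi - lo + 1L < 8L)) return(out)
  sub <- vals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_mk <- mk[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- hi - lo + 1L
  dim(sub) <- dim(sub_mk) <- d
  pad_even <- function(x, fill_edge = TRUE) {
    d <- dim(x)
    tgt <- d + d %% 2L
    if (all(tgt == d)) return(x)
    out <- array(if (is.logical(x)) FALSE else 0, tgt)
    out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
    if (fill_edge && !is.logical(x)) {
      if (tgt[1] > d[1]) out[tgt[1], , ] <- out[d[1], , ]
      if (tgt[2] > d[2]) out[, tgt[2], ] <- out[, d[2], ]
      if (tgt[3] > d[3]) out[, , tgt[3]] <- out[, , d[3]]
    }
    out
  }
  sub <- pad_even(sub)
  sub_mk <- pad_even(sub_mk)
  # downsampled mask support: any mask voxel in each 2x2x2 block
  dd <- dim(sub_mk)
  blk <- array(FALSE, dd %/% 2L)
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    blk <- blk | sub_mk[seq(1 + ox, dd[1], 2), seq(1 + oy, dd[2], 2),
                        seq(1 + oz, dd[3], 2), drop = FALSE]
  }
  sx <- haar_step_axis(sub, 1L)
  for (b in bands) {
    letters3 <- strsplit(b, "")[[1]]
    cur <- sx[[letters3[1]]]
    cur <- haar_step_axis(cur, 2L)[[letters3[2]]]
    cur <- haar_step_axis(cur, 3L)[[letters3[3]]]
    v <- cur[blk]
    out[paste0("Wavelet_", b)] <- if (length(v)) mean(abs(v)) else NA_real_
  }
  out
}
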