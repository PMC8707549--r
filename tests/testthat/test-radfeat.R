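test_that("quantization maps intensities to equal-width levels", {
  vol <- array(-800, dim = c(6, 6, 3))
  mk <- array(FALSE, dim = c(6, 6, 3))
  mk[2:5, 2:5, 2] <- TRUE

  # constant ROI: everything level 1
  q <- quantize_roi(vol, mk, 8)
  expect_true(all(q$levels[q$levels > 0] == 1L))

  # exact bin boundaries
  vol[mk] <- rep(c(0, 1, 2, 3), 4)
  q <- quantize_roi(vol, mk, 4)
  expect_identical(sort(unique(q$levels[q$levels > 0])), 1:4)
  expect_identical(as.integer(table(q$levels[q$levels > 0])), rep(4L, 4))

  # histogram of levels sums to the mask voxel count
  set.seed(8)
  vol[mk] <- rnorm(16)
  q <- quantize_roi(vol, mk, 5)
  expect_identical(sum(tabulate(q$levels[q$levels > 0], 5)), 16L)
  expect_true(all(diff(q$bin_edges) > 0))

  expect_error(quantize_roi(vol, array(FALSE, dim(vol)), 4), "empty")
  expect_error(quantize_roi(vol, mk, 1), "n_levels")
})

test_that("GLCM features match closed forms and exhaustive enumeration", {
  # constant ROI: a single co-occurrence cell, entropies 0
  q <- new_qroi(array(1L, dim = c(3, 3, 3)), 4)
  f <- glcm_features(q)
  expect_identical(f[["GLCM_Entropy"]], 0)
  expect_identical(f[["GLCM_Diff_Entropy"]], 0)
  expect_identical(f[["GLCM_Energy"]], 1)

  # 4x4x1 checkerboard: enumerate pairs by hand via the oracle
  cb <- array(0L, dim = c(4, 4, 1))
  cb[, , 1] <- (outer(1:4, 1:4, `+`) %% 2L) + 1L
  q <- new_qroi(cb, 2)
  M <- oracle_glcm_matrix(cb, 2)
  f <- glcm_features(q)
  expect_equal(f[["GLCM_Entropy"]], oracle_entropy_bits(M / sum(M)))
  pd <- c(sum(diag(M)), M[1, 2] + M[2, 1])
  expect_equal(f[["GLCM_Diff_Entropy"]], oracle_entropy_bits(pd / sum(pd)))

  # random ROIs match enumeration exactly
  for (seed in 1:20) {
    q <- random_qroi(seed)
    M <- oracle_glcm_matrix(q$levels, q$n_levels)
    f <- glcm_features(q)
    if (sum(M) == 0) {
      expect_true(is.na(f[["GLCM_Entropy"]]))
      next
    }
    p <- M / sum(M)
    i <- row(p); j <- col(p)
    expect_equal(f[["GLCM_Entropy"]], oracle_entropy_bits(p))
    expect_equal(f[["GLCM_Contrast"]], sum(p * (i - j)^2))
    expect_equal(f[["GLCM_Homogeneity"]], sum(p / (1 + abs(i - j))))
    expect_equal(f[["GLCM_Energy"]], sum(p^2))
  }
})

test_that("GLRLM features match closed forms and run enumeration", {
  # constant 1x1xN line, single direction along the run
  N <- 6L
  line <- array(1L, dim = c(1, 1, N))
  q <- new_qroi(line, 2)
  f <- glrlm_features(q, directions = matrix(c(0, 0, 1), 1))
  expect_equal(f[["Run_SPE"]], 1 / N^2)
  expect_equal(f[["Run_PP"]], 1 / N)

  # strictly alternating line: all runs length 1
  alt <- array(rep(c(1L, 2L), 3), dim = c(1, 1, N))
  q <- new_qroi(alt, 2)
  f <- glrlm_features(q, directions = matrix(c(0, 0, 1), 1))
  expect_equal(f[["Run_SPE"]], 1)
  expect_equal(f[["Run_PP"]], 1)

  # random ROIs against the brute-force run scan, all 13 directions
  for (seed in 21:35) {
    q <- random_qroi(seed)
    got <- glrlm_features(q)
    want <- oracle_glrlm_features(q$levels, q$n_levels)
    expect_equal(unname(got),
                 unname(want[c("SPE", "LRE", "PP", "GLN", "RLN")]))
  }
})

test_that("GLSZM features match the connected-component oracle", {
  # two disjoint single-voxel zones of the same level
  lv <- array(0L, dim = c(5, 5, 1))
  lv[1, 1, 1] <- 1L
  lv[5, 5, 1] <- 1L
  q <- new_qroi(lv, 2)
  z <- radkern:::glszm_zones(q)
  expect_identical(sum(z$size == 1L), 2L)

  # all-distinct levels: every voxel is its own zone (26-connectivity makes a
  # two-level checkerboard diagonally connected, so distinct levels are the
  # clean zones-equal-voxels case)
  ln <- array(0L, dim = c(4, 4, 1))
  ln[, , 1] <- matrix(1:16, 4)
  f <- glszm_features(new_qroi(ln, 16))
  expect_equal(f[["SizeZone_ZP"]], 1)
  expect_equal(f[["SizeZone_SZE"]], 1)

  # constant ROI: one zone covering the mask
  q <- new_qroi(array(1L, dim = c(3, 3, 2)), 2)
  f <- glszm_features(q)
  expect_equal(f[["SizeZone_LZE"]], 18^2)
  expect_equal(f[["SizeZone_ZP"]], 1 / 18)

  for (seed in 41:55) {
    q <- random_qroi(seed)
    zo <- oracle_glszm_zones(q$levels)
    nz <- length(zo$size)
    np <- sum(q$levels > 0)
    f <- glszm_features(q)
    expect_equal(f[["SizeZone_SZE"]], mean(1 / zo$size^2))
    expect_equal(f[["SizeZone_LZE"]], mean(zo$size^2))
    expect_equal(f[["SizeZone_ZP"]], nz / np)
    expect_equal(f[["SizeZone_GLN"]],
                 sum(tabulate(zo$level, q$n_levels)^2) / nz)
  }
})

test_that("NGTDM handles degenerate and uniform neighborhoods", {
  # constant ROI: all s_i = 0 so coarseness hits the documented cap
  lv <- array(1L, dim = c(5, 5, 5))
  f <- ngtdm_features(new_qroi(lv, 3))
  expect_equal(f[["NGTDM_Coarseness"]], 1e12)

  # no voxel with a complete 26-neighborhood: undefined, flagged
  f2 <- ngtdm_features(new_qroi(array(1L, dim = c(2, 2, 2)), 2))
  expect_true(all(is.na(f2)))

  # hand-checkable 3x3x3 with one center voxel differing
  lv[2:4, 2:4, 2:4] <- 1L
  lv[3, 3, 3] <- 2L
  f3 <- ngtdm_features(new_qroi(lv, 2))
  # 27 interior voxels have complete neighborhoods (5^3 grid -> 3^3 interior)
  # center voxel: |2 - (26*1)/26| = 1; its 26 neighbors see mean (25*1+2)/26
  expect_true(is.finite(f3[["NGTDM_Coarseness"]]))
  expect_gt(f3[["NGTDM_Contrast"]], 0)
})

test_that("intensity features follow direct moment arithmetic", {
  vol <- array(0, dim = c(8, 8, 3))
  mk <- array(FALSE, dim = c(8, 8, 3))
  mk[2:7, 2:7, 2] <- TRUE  # 36 voxels in one slice

  # symmetric values: zero skewness
  vol[mk] <- rep(c(-1, 0, 1), 12)
  f <- intensity_features(vol, mk)
  expect_equal(f[["Intensity_Skewness_3D"]], 0)
  # single-slice ROI: 2D equals 3D
  expect_equal(f[["Intensity_Skewness_2D"]], f[["Intensity_Skewness_3D"]])

  # {0,0,0,1} repeated: direct moment oracle
  vol[mk] <- rep(c(0, 0, 0, 1), 9)
  f <- intensity_features(vol, mk)
  x <- rep(c(0, 0, 0, 1), 9)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  expect_equal(f[["Intensity_Skewness_3D"]], m3 / m2^1.5)

  # constant ROI: zero-variance conventions
  vol[mk] <- 5
  f <- intensity_features(vol, mk)
  expect_identical(f[["Intensity_Skewness_3D"]], 0)
  expect_identical(f[["Intensity_Kurtosis"]], 0)
  expect_identical(f[["Intensity_Entropy"]], 0)
})

test_that("LoG kernel and responses match the convolution oracle", {
  for (sigma in c(1.5, 2.5)) {
    k <- radkern:::log_kernel(sigma)
    expect_lt(abs(sum(k)), 1e-6)
  }

  # constant volume: responses vanish, entropy 0 under the single-bin rule
  vol <- array(3, dim = c(24, 24, 24))
  mk <- array(FALSE, dim = dim(vol))
  mk[10:15, 10:15, 10:15] <- TRUE
  f <- log_features(vol, mk, sigmas = 1.5)
  expect_identical(f[["LoG_Entropy_p1"]], 0)
  expect_lt(abs(f[["LoG_Mean_p1"]]), 1e-8)

  # isolated unit impulse: response at center equals the kernel center value
  vol <- array(0, dim = c(24, 24, 24))
  vol[12, 12, 12] <- 1
  k <- radkern:::log_kernel(1.5)
  resp <- radkern:::conv3d_fft(vol, k)
  ctr <- (dim(k) + 1) / 2
  expect_equal(resp[12, 12, 12], k[ctr[1], ctr[2], ctr[3]], tolerance = 1e-10)

  # oversized kernel is rejected
  expect_error(log_features(vol, mk, sigmas = 4), "larger than the volume")
})

test_that("edge features equal direct finite differences", {
  vol <- array(7, dim = c(10, 10, 6))
  mk <- array(FALSE, dim = dim(vol))
  mk[3:8, 3:8, 2:5] <- TRUE
  expect_identical(edge_freq_mean(vol, mk), 0)

  # linear ramp of slope g along x: interior gradient is exactly g
  g <- 4.2
  for (i in 1:10) vol[i, , ] <- g * i
  mk_int <- array(FALSE, dim = dim(vol))
  mk_int[3:8, 3:8, 2:5] <- TRUE
  expect_equal(edge_freq_mean(vol, mk_int), g)

  # random volume vs an independently coded central-difference oracle
  set.seed(1)
  vol <- array(rnorm(600), dim = c(10, 10, 6))
  d <- dim(vol)
  idx <- which(mk_int, arr.ind = TRUE)
  oracle_gm <- apply(idx, 1, function(v) {
    cd <- function(axis) {
      lo <- v; hi <- v
      hi[axis] <- min(hi[axis] + 1, d[axis])
      lo[axis] <- max(lo[axis] - 1, 1)
      (vol[hi[1], hi[2], hi[3]] - vol[lo[1], lo[2], lo[3]]) /
        (hi[axis] - lo[axis])
    }
    sqrt(cd(1)^2 + cd(2)^2 + cd(3)^2)
  })
  expect_equal(edge_freq_mean(vol, mk_int), mean(oracle_gm))
})

test_that("shape features match closed forms", {
  mk <- array(FALSE, dim = c(5, 5, 5))
  mk[3, 3, 3] <- TRUE
  f <- shape_features(mk, spacing = c(1, 1, 1))
  expect_equal(f[["Shape_Volume_mm3"]], 1)
  expect_equal(f[["Shape_SurfaceArea_mm2"]], 6)
  expect_equal(f[["Shape_MaxDiameter3D_mm"]], 0)

  mk[2:4, 2:4, 2:4] <- TRUE
  f <- shape_features(mk, spacing = c(1, 1, 1))
  expect_equal(f[["Shape_Volume_mm3"]], 27)
  expect_equal(f[["Shape_SurfaceArea_mm2"]], 54)
  expect_equal(f[["Shape_MaxDiameter3D_mm"]], 2 * sqrt(3))
  expect_equal(f[["Shape_Compactness"]], 36 * pi * 27^2 / 54^3)

  # anisotropic spacing
  f2 <- shape_features(mk, spacing = c(1, 1, 2))
  expect_equal(f2[["Shape_Volume_mm3"]], 54)
})

test_that("sigmoid slope recovers logistic edges and orders blur widths", {
  n <- 33
  ctr <- c(17, 17, 17)
  ax <- 1:n
  rr <- sqrt(outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, `+`),
                   (ax - ctr[3])^2, `+`))
  dim(rr) <- c(n, n, n)
  mk <- rr <= 8

  # exact logistic profile with known parameters: the profile fitter recovers
  # the maximum slope b/(4s) to better than 1e-3 relative
  b <- -300; s <- 1.5; t0 <- 8
  tt <- seq(0, 14, by = 0.5)
  prof <- 200 + b / (1 + exp(-(tt - t0) / s))
  expect_equal(radkern:::fit_sigmoid_profile(tt, prof), b / (4 * s),
               tolerance = 1e-3)

  # whole-volume estimate: radial logistic sampled by trilinear interpolation
  vol <- 200 + b / (1 + exp(-(rr - t0) / s))
  got <- sigmoid_slope(vol, mk)
  expect_equal(got, b / (4 * s), tolerance = 0.05)

  # recovered slope magnitude decreases monotonically with blur width
  slopes <- sapply(c(0.8, 1.6, 3.2), function(sw) {
    v <- 200 + b / (1 + exp(-(rr - t0) / sw))
    abs(sigmoid_slope(v, mk))
  })
  expect_true(all(diff(slopes) < 0))

  # constant volume has no edge: undefined
  expect_true(is.na(sigmoid_slope(array(1, dim = c(n, n, n)), mk)))
})

test_that("Laws and wavelet energies obey kernel arithmetic and linearity", {
  vol <- array(2.5, dim = c(12, 12, 12))
  mk <- array(FALSE, dim = dim(vol))
  mk[3:10, 3:10, 3:10] <- TRUE

  f <- laws_features(vol, mk)
  expect_equal(f[["Laws_L5L5L5"]], 2.5 * 16^3)  # sum(L5) = 16 per axis
  expect_identical(f[["Laws_E5E5E5"]], 0)
  expect_identical(f[["Laws_S5S5S5"]], 0)

  w <- wavelet_features(vol, mk)
  expect_equal(w[["Wavelet_LLL"]], 2.5 * 2^1.5)
  expect_true(all(w[grep("H", names(w))] == 0))

  # homogeneity of degree 1 in intensity scale
  set.seed(2)
  vol2 <- array(rnorm(12^3), dim = dim(vol))
  f1 <- laws_features(vol2, mk)
  f2 <- laws_features(2 * vol2, mk)
  expect_equal(unname(f2), unname(2 * f1))
  w1 <- wavelet_features(vol2, mk)
  w2 <- wavelet_features(2 * vol2, mk)
  expect_equal(unname(w2), unname(2 * w1))
  e1 <- edge_freq_features(vol2, mk)
  e2 <- edge_freq_features(2 * vol2, mk)
  expect_equal(unname(e2), unname(2 * e1))

  # undersized bounding box flags wavelet features undefined
  mk_small <- array(FALSE, dim = dim(vol))
  mk_small[5:8, 5:8, 5:8] <- TRUE
  expect_true(all(is.na(wavelet_features(vol, mk_small))))
})

test_that("quantized texture features are invariant to bin-preserving affine maps", {
  set.seed(3)
  vol <- array(0, dim = c(8, 8, 8))
  mk <- array(FALSE, dim = dim(vol))
  mk[2:7, 2:7, 2:7] <- TRUE
  vol[mk] <- sample(1:6, sum(mk), replace = TRUE)
  q1 <- quantize_roi(vol, mk, 6)
  q2 <- quantize_roi(100 + 3 * vol, mk, 6)
  expect_identical(q1$levels, q2$levels)
  expect_identical(glcm_features(q1), glcm_features(q2))
  expect_identical(glrlm_features(q1), glrlm_features(q2))
})

test_that("extract_all covers the registry deterministically", {
  reg_core <- feature_registry("core")
  expect_gte(nrow(reg_core), 40)
  expect_identical(sort(unique(reg_core$family)),
                   sort(c("shape", "intensity", "glcm", "glrlm", "glszm",
                          "ngtdm", "log", "edge", "laws", "wavelet",
                          "sharpness")))
  reg_ext <- feature_registry("extended")
  expect_identical(nrow(reg_ext), 89L)
  expect_identical(dplyr::n_distinct(reg_ext$group), 23L)
  expect_false(anyDuplicated(reg_ext$feature) > 0)

  rec <- small_cohort(n = 2, seed = 19)$records[[1]]
  cfg <- extractor_config("core")
  fv1 <- extract_all(rec$smooth_image, rec$mask, cfg)
  fv2 <- extract_all(rec$smooth_image, rec$mask, cfg)
  expect_identical(fv1$value, fv2$value)
  expect_identical(fv1$feature, cfg$registry$feature)
  expect_true(all(is.finite(fv1$value)))

  # entropy features live inside their theoretical bounds
  ent <- fv1$value[grepl("Entropy", fv1$feature)]
  expect_true(all(ent >= 0))
  expect_true(all(ent <= 2 * log2(32)))
})
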