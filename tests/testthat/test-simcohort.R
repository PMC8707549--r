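test_that("phantom lesion texture behaves as specified", {
  sp <- small_spec(texture_contrast = 0)
  ph <- generate_phantom(sp, 0, seed = 3)
  inside <- ph$truth$values[ph$mask$values]
  expect_true(all(inside == sp$lesion_level))
  expect_true(all(ph$truth$values[!ph$mask$values] == sp$background_level))
  expect_gte(sum(ph$mask$values), 27)

  # determinism
  sp2 <- small_spec()
  a <- generate_phantom(sp2, 1, seed = 11)
  b <- generate_phantom(sp2, 1, seed = 11)
  expect_identical(a$truth$values, b$truth$values)
  expect_identical(a$mask$values, b$mask$values)

  expect_error(generate_phantom(sp2, 2, seed = 1), "label")
  expect_error(phantom_spec(grid_shape = c(16, 16, 8), lesion_radius = 8),
               "margin")
})

test_that("label_effect shifts the lesion texture distribution", {
  sp <- small_spec(label_effect = 1.5)
  vars <- sapply(0:1, function(lab) {
    sapply(1:50, function(i) {
      ph <- generate_phantom(sp, lab, seed = 1000 * lab + i)
      stats::var(ph$truth$values[ph$mask$values])
    })
  })
  expect_gt(mean(vars[, 2]), mean(vars[, 1]))
  expect_lt(t.test(vars[, 2], vars[, 1])$p.value, 0.01)
})

test_that("kernel rendering is an exact radial frequency filter", {
  sp <- small_spec()
  ph <- generate_phantom(sp, 0, seed = 5)

  ident <- kernel_profile("id", mtf_gain = 0, mtf_cutoff = 0.2, noise_sigma = 0)
  out <- apply_kernel(ph$truth, ident, seed = 1)
  expect_lt(max(abs(out$values - ph$truth$values)), 1e-8)

  # DC conservation for a noise-free sharpening kernel
  boost <- kernel_profile("sharp0", 1.5, 0.2, 0)
  out2 <- apply_kernel(ph$truth, boost, seed = 1)
  expect_lt(abs(mean(out2$values) - mean(ph$truth$values)) /
              abs(mean(ph$truth$values)), 1e-8)

  # distinct profiles give a nonzero difference
  smo <- apply_kernel(ph$truth, smooth_profile(), seed = 2)
  shp <- apply_kernel(ph$truth, sharp_profile(), seed = 3)
  expect_gt(rmse(smo, shp), 0)
})

test_that("pure sinusoid is scaled by the closed-form ramp response", {
  n <- 32
  g <- 1.2
  cutoff <- 0.2
  for (k in c(2, 5, 10)) {
    f0 <- k / n
    slice <- matrix(sin(2 * pi * f0 * (0:(n - 1))), n, n)
    vol <- array(rep(slice, 2), dim = c(n, n, 2))
    kern <- kernel_profile("boost", g, cutoff, 0)
    out <- apply_kernel(vol, kern, seed = 1)
    # measure the output amplitude at f0 via the DFT bin
    co <- fft(out$values[, 1, 1])
    amp <- 2 * Mod(co[k + 1]) / n
    u <- f0 / cutoff
    expected <- 1 * (1 + g * u^2 / (1 + u^2))
    expect_equal(amp, expected, tolerance = 1e-10)
  }
})

test_that("cohort generation honours prevalence, determinism and mask sharing", {
  coh <- small_cohort(n = 10, seed = 7, prevalence = 0.5)
  labs <- vapply(coh$records, `[[`, integer(1), "label")
  expect_identical(sum(labs), 5L)

  coh2 <- small_cohort(n = 10, seed = 7, prevalence = 0.5)
  expect_identical(coh$records[[3]]$smooth_image$values,
                   coh2$records[[3]]$smooth_image$values)
  expect_identical(coh$records[[3]]$sharp_image$values,
                   coh2$records[[3]]$sharp_image$values)

  expect_error(generate_cohort(1, 0.5, small_spec(), smooth_profile(),
                               sharp_profile(), 1), "n must be >= 2")
  expect_error(generate_cohort(4, 1.2, small_spec(), smooth_profile(),
                               sharp_profile(), 1), "prevalence")

  ids <- vapply(coh$records, `[[`, character(1), "id")
  expect_false(anyDuplicated(ids) > 0)
  # the mask is one object shared across both renderings of a record
  rec <- coh$records[[1]]
  expect_identical(dim(rec$mask$values), dim(rec$smooth_image$values))
  expect_identical(dim(rec$mask$values), dim(rec$sharp_image$values))
})

test_that("cohorts round-trip through NIfTI plus manifest", {
  dir <- withr::local_tempdir()
  coh <- small_cohort(n = 3, seed = 21)
  mf <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "generation_params.json")))
  back <- read_cohort(dir)
  expect_identical(length(back$records), 3L)
  expect_identical(
    vapply(back$records, `[[`, integer(1), "label"),
    vapply(coh$records, `[[`, integer(1), "label")
  )
  expect_identical(back$records[[2]]$mask$values, coh$records[[2]]$mask$values)
  # float32 round trip
  expect_lt(max(abs(back$records[[2]]$smooth_image$values -
                      coh$records[[2]]$smooth_image$values)), 1e-3)
  expect_identical(back$records[[2]]$smooth_image$spacing,
                   coh$records[[2]]$smooth_image$spacing)
})

test_that("a 223-patient cohort at prevalence 114/223 has 114 positive labels", {
  sp <- phantom_spec(grid_shape = c(16, 16, 10), lesion_radius = 2,
                     lesion_radius_jitter = 0, texture_correlation_length = 1)
  coh <- generate_cohort(223, 114 / 223, sp, smooth_profile(),
                         sharp_profile(), seed = 2)
  labs <- vapply(coh$records, `[[`, integer(1), "label")
  expect_identical(sum(labs == 1L), 114L)
  expect_identical(sum(labs == 0L), 109L)
})
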