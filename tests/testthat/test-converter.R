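test_that("untrained converter is the exact identity and builds deterministically", {
  cfg <- converter_config("to_smooth", n_layers = 4, channels = 8, seed = 9)
  m <- build_converter(cfg)
  vol <- small_cohort(n = 2, seed = 4)$records[[1]]$sharp_image
  out <- convert_volume(m, vol)
  expect_identical(out$values, vol$values)

  m2 <- build_converter(cfg)
  expect_identical(m$layers, m2$layers)
  m3 <- build_converter(converter_config("to_smooth", n_layers = 4,
                                         channels = 8, seed = 10))
  expect_false(identical(m$layers, m3$layers))

  expect_error(converter_config("to_smooth", n_layers = 1), "n_layers")
})

test_that("parameter count matches the closed-form 3x3 stack arithmetic", {
  count_for <- function(L, C) {
    # first layer 1->C, middle layers C->C, last layer C->1, each 3x3 + bias
    (9 * 1 * C + C) + (L - 2) * (9 * C * C + C) + (9 * C * 1 + 1)
  }
  for (case in list(c(6, 64), c(4, 8), c(2, 16))) {
    m <- build_converter(converter_config("to_sharp", n_layers = case[1],
                                          channels = case[2]))
    expect_identical(n_parameters(m), count_for(case[1], case[2]))
  }
})

test_that("rmse and rmse_reduction follow their closed forms", {
  x <- array(rnorm(60), dim = c(5, 4, 3))
  expect_identical(rmse(x, x), 0)
  expect_equal(rmse(x, x + 2.5), 2.5)
  expect_equal(rmse_reduction(x + 1, x, x), 100)
  expect_warning(red <- rmse_reduction(x, x + 1, x), "undefined")
  expect_identical(red, 0)
  expect_error(rmse(x, x[, , 1:2]), "shape mismatch")
})

test_that("training reduces loss and is reproducible", {
  coh <- small_cohort(n = 3, seed = 13)
  cfg <- converter_config("to_smooth", n_layers = 3, channels = 4,
                          learning_rate = 1e-3, n_epochs = 6, seed = 2)
  pairs <- cohort_slice_pairs(coh, "to_smooth", slices = 10:14)
  m <- train_converter(pairs, cfg)
  expect_identical(nrow(m$training_log), 6L)
  expect_true(all(is.finite(m$training_log$test_loss)))
  expect_lt(m$training_log$test_loss[6], m$initial_test_loss)

  m2 <- train_converter(pairs, cfg)
  expect_identical(m$layers, m2$layers)
  expect_identical(m$training_log, m2$training_log)

  # converting a held-out volume moves it toward the target rendering
  rec <- small_cohort(n = 2, seed = 77)$records[[1]]
  conv <- convert_volume(m, rec$sharp_image)
  expect_lt(rmse(conv, rec$smooth_image), rmse(rec$sharp_image, rec$smooth_image))
})

test_that("degenerate source-equals-target training stays near the identity", {
  coh <- small_cohort(n = 2, seed = 31)
  slc <- volume_values(coh$records[[1]]$smooth_image)[, , 10:13]
  pairs <- lapply(1:4, function(i) list(source = slc[, , i], target = slc[, , i]))
  cfg <- converter_config("to_smooth", n_layers = 2, channels = 4,
                          learning_rate = 1e-4, n_epochs = 4, seed = 5)
  m <- train_converter(pairs, cfg, holdout_fraction = 0.25)
  expect_lt(m$initial_test_loss, 1e-12)
  expect_lte(m$training_log$test_loss[4], 1e-8)
})

test_that("converter guards its inputs", {
  cfg <- converter_config("to_smooth", n_layers = 2, channels = 2)
  m <- build_converter(cfg)
  bad <- array(c(NA, rnorm(7)), dim = c(2, 2, 2))
  expect_error(convert_volume(m, bad), "non-finite")
  expect_error(train_converter(list(), cfg), "at least 2")
  p1 <- list(source = matrix(0, 4, 4), target = matrix(0, 4, 4))
  p2 <- list(source = matrix(0, 5, 5), target = matrix(0, 5, 5))
  expect_error(train_converter(list(p1, p2), cfg), "share one shape")

  # a constant volume stays finite under an untrained and a perturbed model
  const <- array(100, dim = c(8, 8, 3))
  expect_true(all(is.finite(convert_volume(m, const))))
})

test_that("converters serialize to a single file and back", {
  dir <- withr::local_tempdir()
  cfg <- converter_config("to_sharp", n_layers = 2, channels = 2, seed = 3)
  m <- build_converter(cfg)
  path <- file.path(dir, "model.rds")
  save_converter(m, path)
  back <- load_converter(path)
  expect_identical(back$layers, m$layers)
  expect_identical(back$config$direction, "to_sharp")
  saveRDS(1:3, file.path(dir, "junk.rds"))
  expect_error(load_converter(file.path(dir, "junk.rds")), "not a kernel converter")
})
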