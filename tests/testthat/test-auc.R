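test_that("univariate AUC equals the exhaustive U-statistic", {
  expect_identical(univariate_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_identical(univariate_auc(c(1, 3, 2, 4), c(0, 0, 1, 1),
                                  orientation_correct = FALSE), 0.75)
  # all values tied: 0.5 before orientation correction
  expect_identical(univariate_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1),
                                  orientation_correct = FALSE), 0.5)

  set.seed(15)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    labs <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labs)) < 2) labs[1:2] <- c(0, 1)
    vals <- sample(1:8, n, replace = TRUE)  # plenty of ties
    a <- univariate_auc(vals, labs, orientation_correct = FALSE)
    expect_equal(a, oracle_auc(vals, labs))
    expect_gte(univariate_auc(vals, labs), 0.5)
  }

  expect_error(univariate_auc(c(1, 2, 3, 4), c(1, 1, 1, 1)), "both classes")
  expect_error(univariate_auc(1:3, c(0, 1, 0)), "at least 4")
})

test_that("mixed assignment splits near-evenly and reproducibly", {
  fake_cohort <- function(n) {
    structure(list(records = lapply(seq_len(n), function(i) {
      list(id = sprintf("P%03d", i))
    })), class = "kernel_cohort")
  }
  a223 <- assign_mixed(fake_cohort(223), seed = 4)
  expect_identical(sum(a223$arm == "smooth"), 111L)
  expect_identical(sum(a223$arm == "sharp"), 112L)

  a10 <- assign_mixed(fake_cohort(10), seed = 4)
  expect_identical(sum(a10$arm == "smooth"), 5L)

  expect_identical(assign_mixed(fake_cohort(50), seed = 7)$arm,
                   assign_mixed(fake_cohort(50), seed = 7)$arm)
  expect_false(identical(assign_mixed(fake_cohort(50), seed = 7)$arm,
                         assign_mixed(fake_cohort(50), seed = 8)$arm))
})

test_that("mix_feature_tables swaps exactly the assigned rows", {
  ids <- sprintf("P%02d", 1:6)
  mk_tab <- function(v, setting) {
    tab <- tibble::tibble(patient_id = ids, f1 = v, f2 = v * 2)
    attr(tab, "setting") <- setting
    tab
  }
  ori_smo <- mk_tab(rep(1, 6), "ori_smo")
  ori_shp <- mk_tab(rep(2, 6), "ori_shp")
  conv_smo <- mk_tab(rep(3, 6), "conv_smo")
  conv_shp <- mk_tab(rep(4, 6), "conv_shp")
  assignment <- structure(
    tibble::tibble(patient_id = ids,
                   arm = c("smooth", "sharp", "smooth", "sharp", "smooth",
                           "sharp")),
    class = c("mixed_assignment", "tbl_df", "tbl", "data.frame"), seed = 1)

  mixed <- mix_feature_tables(ori_smo, ori_shp, conv_smo, conv_shp, assignment)
  expect_identical(mixed$ori_mix$f1, c(1, 2, 1, 2, 1, 2))
  expect_identical(mixed$conv_mix_smo$f1, c(1, 3, 1, 3, 1, 3))
  expect_identical(mixed$conv_mix_shp$f1, c(4, 2, 4, 2, 4, 2))

  # all patients in the smooth arm: ori_mix equals conv_mix_smo exactly
  assignment_all <- structure(
    tibble::tibble(patient_id = ids, arm = rep("smooth", 6)),
    class = c("mixed_assignment", "tbl_df", "tbl", "data.frame"), seed = 1)
  mixed_all <- mix_feature_tables(ori_smo, ori_shp, conv_smo, conv_shp,
                                  assignment_all)
  expect_equal(as.data.frame(mixed_all$ori_mix),
               as.data.frame(mixed_all$conv_mix_smo), ignore_attr = TRUE)
})

test_that("identity converters collapse the converted groups onto the originals", {
  coh <- small_cohort(n = 4, seed = 23)
  assignment <- assign_mixed(coh, seed = 3)
  to_smo <- build_converter(converter_config("to_smooth", n_layers = 2,
                                             channels = 2))
  to_shp <- build_converter(converter_config("to_sharp", n_layers = 2,
                                             channels = 2))
  cfg <- extractor_config("core")
  tabs <- build_groups(coh, assignment, to_smo, to_shp, cfg)
  expect_equal(as.data.frame(tabs$ori_mix),
               as.data.frame(tabs$conv_mix_smo), ignore_attr = TRUE)
  expect_equal(as.data.frame(tabs$ori_mix),
               as.data.frame(tabs$conv_mix_shp), ignore_attr = TRUE)
  expect_identical(tabs$ori_mix$patient_id, assignment$patient_id)

  # direction mismatch is rejected
  expect_error(build_groups(coh, assignment, to_shp, to_smo, cfg),
               "wrong direction")

  # equal groups: the signed-rank comparisons report no difference
  labels <- cohort_labels(coh)
  rep <- auc_distribution(tabs, labels)
  expect_true(all(rep$comparisons$no_difference))
  expect_true(all(rep$comparisons$p.value == 1))
})

test_that("auc_distribution summarizes with median and unscaled MAD", {
  v <- c(0.5, 0.6, 0.7)
  expect_identical(median(v), 0.6)
  expect_equal(mad(v, constant = 1), 0.1)

  # permuting patient order changes nothing
  ids <- sprintf("P%02d", 1:20)
  set.seed(16)
  mk_tab <- function(setting) {
    tab <- tibble::tibble(patient_id = ids,
                          f1 = rnorm(20), f2 = rnorm(20), f3 = rnorm(20),
                          f4 = rnorm(20), f5 = rnorm(20), f6 = rnorm(20))
    attr(tab, "setting") <- setting
    tab
  }
  tabs <- structure(list(ori_mix = mk_tab("ori_mix"),
                         conv_mix_smo = mk_tab("conv_mix_smo"),
                         conv_mix_shp = mk_tab("conv_mix_shp")),
                    class = "grouped_feature_tables")
  labels <- stats::setNames(rep(c(0L, 1L), 10), ids)
  rep1 <- auc_distribution(tabs, labels)

  perm <- sample(20)
  tabs2 <- tabs
  for (nm in names(tabs2)) {
    st <- attr(tabs2[[nm]], "setting")
    tabs2[[nm]] <- tabs2[[nm]][perm, ]
    attr(tabs2[[nm]], "setting") <- st
  }
  rep2 <- auc_distribution(tabs2, labels)
  expect_identical(rep1$aucs, rep2$aucs)
  expect_identical(rep1$summary, rep2$summary)

  expect_error(auc_distribution(tabs, unname(labels)), "named vector")
})

test_that("label shuffling removes any systematic conversion gain", {
  # under permuted labels the converted group must show no AUC advantage:
  # guards against information leaking through the converter
  exp_report <- acceptance_experiment()
  mixed <- mix_feature_tables(
    exp_report$feature_tables$ori_smo, exp_report$feature_tables$ori_shp,
    exp_report$feature_tables$conv_smo, exp_report$feature_tables$conv_shp,
    exp_report$assignment
  )
  ids <- mixed$ori_mix$patient_id
  labs <- cohort_labels(generate_cohort(
    exp_report$config$val_n, exp_report$config$prevalence,
    exp_report$config$spec, exp_report$config$val_smooth,
    exp_report$config$val_sharp, radkern:::derive_seed(exp_report$config$seed, "val")))
  set.seed(17)
  deltas <- replicate(100, {
    shuffled <- stats::setNames(sample(unname(labs)), ids)
    a_ori <- radkern:::group_auc_vector(mixed$ori_mix, shuffled)
    a_conv <- radkern:::group_auc_vector(mixed$conv_mix_smo, shuffled)
    mean(a_conv - a_ori, na.rm = TRUE)
  })
  expect_lt(abs(mean(deltas)), 0.01)
})
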