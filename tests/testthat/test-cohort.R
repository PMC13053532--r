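test_that("the default cohort has 43 records, 22 of them C-shaped", {
  co <- sample_cohort(cohort_spec(seed = 1))
  expect_equal(nrow(co), 43)
  expect_equal(sum(co$c_shaped), 22)
  expect_equal(sum(!co$c_shaped), 21)
  tab <- table(co$resolution_group, co$c_shaped)
  expect_equal(unname(tab["1023x496", "TRUE"]), 10)
  expect_equal(unname(tab["1023x496", "FALSE"]), 16)
  expect_equal(unname(tab["1023x593", "TRUE"]), 12)
  expect_equal(unname(tab["1023x593", "FALSE"]), 5)
})

test_that("identical specs give bit-identical cohorts", {
  a <- sample_cohort(cohort_spec(seed = 33))
  b <- sample_cohort(cohort_spec(seed = 33))
  attr(a, "spec") <- NULL; attr(b, "spec") <- NULL
  expect_identical(a, b)
  c <- sample_cohort(cohort_spec(seed = 34))
  expect_false(identical(a$xpar_non_zoomed, c$xpar_non_zoomed))
})

test_that("empty and misconfigured specs are handled", {
  empty <- sample_cohort(cohort_spec(0, 0, list(group_496 = c(0L, 0L),
                                                group_593 = c(0L, 0L))))
  expect_equal(nrow(empty), 0)
  expect_error(cohort_spec(10, 10, list(group_496 = c(9L, 5L),
                                        group_593 = c(2L, 5L))),
               "disagree")
  expect_error(cohort_spec(zoom_factor_range = c(0.9, 2)), "\\(1, 4\\]")
})

test_that("default generator lands in the observed descriptive bands", {
  co <- sample_cohort(cohort_spec(seed = 1))
  in_pc <- mean(co$pixel_count_non_zoomed >= 1200 &
                co$pixel_count_non_zoomed <= 2700)
  in_xpar <- mean(co$xpar_non_zoomed >= 7.15 & co$xpar_non_zoomed <= 21.43)
  expect_gte(in_pc, 0.9)
  expect_gte(in_xpar, 0.9)
})

test_that("volume covariate carries the designed standardized difference", {
  sp <- cohort_spec(200, 200, NULL, volume_effect_d = 0.9, seed = 12)
  co <- sample_cohort(sp)
  v1 <- co$dentin_pulp_volume[co$c_shaped]
  v0 <- co$dentin_pulp_volume[!co$c_shaped]
  pooled_sd <- sqrt((stats::var(v1) + stats::var(v0)) / 2)
  d_hat <- (mean(v1) - mean(v0)) / pooled_sd
  expect_gt(d_hat, 0.6); expect_lt(d_hat, 1.2)
  # anchored near the emulated group means
  expect_gt(mean(v0), 340); expect_lt(mean(v0), 430)
  expect_gt(mean(v1), 410); expect_lt(mean(v1), 500)
})

test_that("a null cohort makes every texture metric label-independent", {
  sp <- cohort_spec(100, 100, NULL, heterogeneity_effect = 0,
                    volume_effect_d = 0, seed = 7)
  co <- sample_cohort(sp)
  for (m in c("xpar_non_zoomed", "power_xpar_non_zoomed",
              "pixel_count_non_zoomed", "xpar_zoomed", "power_xpar_zoomed",
              "pixel_count_zoomed")) {
    auc <- roc_with_youden(co[[m]], co$c_shaped)$auc
    expect_gte(auc, 0.35); expect_lte(auc, 0.65)
  }
  expect_gte(roc_with_youden(co$power_xpar_non_zoomed, co$c_shaped)$auc, 0.40)
  expect_lte(roc_with_youden(co$power_xpar_non_zoomed, co$c_shaped)$auc, 0.60)
})

test_that("a strong heterogeneity effect is recovered by Power Xpar", {
  sp <- cohort_spec(50, 50, NULL, heterogeneity_effect = 3,
                    volume_effect_d = 0.9, seed = 11)
  co <- sample_cohort(sp, keep_images = FALSE)
  expect_gte(roc_with_youden(co$power_xpar_non_zoomed, co$c_shaped)$auc, 0.80)
})

test_that("the canal-region variance differs materially under the strong effect", {
  # verify the premise of the effect-recovery property from the masks
  set.seed(2)
  var_of <- function(contrast_shift) {
    vs <- sapply(1:25, function(s) {
      pp <- phantom_params(canal_contrast = 28 + contrast_shift,
                           canal_shape = if (contrast_shift > 0) "c_shaped"
                                         else "simple")
      ph <- make_tooth_phantom(pp, rng_seed = s)
      stats::var(ph$image$pixels[ph$canal_mask])
    })
    mean(vs)
  }
  expect_gte(var_of(3 * 6) / var_of(0), 1.5)
})

test_that("zoomed pixel counts are inflated but not exact multiples", {
  co <- sample_cohort(cohort_spec(seed = 1))
  expect_true(all(co$pixel_count_zoomed > co$pixel_count_non_zoomed))
  ratio <- co$pixel_count_zoomed / co$pixel_count_non_zoomed
  expect_gt(mean(ratio), 1.2); expect_lt(mean(ratio), 2.0)
  expect_false(all(ratio == co$zoom_factor^2))
})

test_that("cohort CSV and JSON spec round-trip", {
  co <- sample_cohort(cohort_spec(4, 3, NULL, seed = 2))
  p <- tempfile(fileext = ".csv")
  write_cohort_csv(co, p)
  back <- read_cohort_csv(p)
  expect_equal(back$xpar_non_zoomed, co$xpar_non_zoomed)
  expect_identical(back$c_shaped, co$c_shaped)

  j <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_c_shaped = 4, n_control = 3, seed = 5,
                            heterogeneity_effect = 2),
                       j, auto_unbox = TRUE)
  sp <- read_cohort_spec_json(j)
  expect_s3_class(sp, "cohort_spec")
  expect_equal(sp$n_c_shaped, 4L)
  expect_equal(sp$heterogeneity_effect, 2)
})

test_that("phantom dumps write one PNG per tooth", {
  co <- sample_cohort(cohort_spec(2, 2, NULL, seed = 3), keep_images = TRUE)
  d <- file.path(tempdir(), "phantom_dump")
  paths <- dump_phantoms(co, d)
  expect_true(all(file.exists(paths)))
  expect_equal(length(paths), 4)
})
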