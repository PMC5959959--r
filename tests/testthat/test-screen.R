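# Reference statistics, z-scores, profiles and flags.

make_controls <- function(values, analyte = "A", age_group = ">2y") {
  tibble::tibble(
    sample_id = sprintf("c%02d", seq_along(values)),
    age_group = age_group, analyte = analyte,
    conc_norm = values)
}

test_that("never-detected analytes get the fixed SD and LOD-centred mean", {
  ctrl <- make_controls(rep(0, 46))
  ref <- build_reference(ctrl, lods = tibble::tibble(analyte = "A",
                                                     lod_norm = 2))
  expect_true(ref$not_detected)
  expect_equal(ref$sd_log2, 0.774)
  expect_equal(ref$mean_log2, log2(2))
  expect_identical(ref$n_imputed, ref$n)
})

test_that("degenerate detected cohorts hit the SD floor", {
  ctrl <- make_controls(rep(7, 10))
  ref <- build_reference(ctrl, lods = 1)
  expect_false(ref$not_detected)
  expect_equal(ref$mean_log2, log2(7))
  expect_equal(ref$sd_log2, 0.1)
})

test_that("below-LOD values are imputed at the LOD before the log", {
  ctrl <- make_controls(c(0.5, 0.2, 4, 8, 16))
  ref <- build_reference(ctrl, lods = 1)
  vals <- log2(c(1, 1, 4, 8, 16))
  expect_equal(ref$mean_log2, mean(vals))
  expect_equal(ref$sd_log2, sd(vals))
  expect_identical(ref$n_imputed, 2L)
  expect_error(build_reference(ctrl[0, ], lods = 1),
               class = "oa_reference_error")
})

test_that("z-score rule: five times the LOD scores 3 for undetected analytes", {
  z5 <- zscore(5 * 2, mean_log2 = log2(2), sd_log2 = 0.774, lod_norm = 2)
  expect_equal(z5, 3, tolerance = 0.001)
  # at or below the LOD the imputation pins z to 0
  expect_equal(zscore(2, log2(2), 0.774, 2), 0)
  expect_equal(zscore(0.1, log2(2), 0.774, 2), 0)
  # at the geometric mean of a detected cohort z is 0
  expect_equal(zscore(12, log2(12), 0.5, 1), 0)
  # monotone in concentration
  z <- zscore(c(1, 2, 5, 10, 50), log2(3), 0.5, 1)
  expect_true(all(diff(z) > 0))
})

test_that("reference building recovers generating parameters", {
  panel <- oa_test_panel()
  spec <- cohort_spec(panel)
  coh <- simulate_cohort(spec, seed = 42)
  ref <- build_reference(coh, spec_lods(spec))
  chk <- ref |>
    dplyr::inner_join(spec$analytes, by = c("analyte", "age_group"),
                      suffix = c("_hat", "_true")) |>
    dplyr::filter(.data$present, !.data$not_detected)
  se_mean <- chk$sd_log2_true / sqrt(chk$n)
  se_sd <- chk$sd_log2_true / sqrt(2 * (chk$n - 1))
  expect_gt(nrow(chk), 100)
  expect_true(all(abs(chk$mean_log2_hat - chk$mean_log2_true) <=
                    3 * se_mean))
  expect_true(all(abs(chk$sd_log2_hat - chk$sd_log2_true) <= 3 * se_sd))
})

test_that("profiles flag by threshold and keep every panel analyte", {
  panel <- oa_test_panel()
  spec <- cohort_spec(panel)
  coh <- simulate_cohort(spec, seed = 21)
  ref <- build_reference(coh, spec_lods(spec))
  # a sample at the control geometric means scores ~0 everywhere
  at_mean <- spec$analytes |>
    dplyr::filter(.data$age_group == ">2y") |>
    dplyr::transmute(analyte = .data$analyte,
                     conc_norm = ifelse(.data$present, 2^.data$mean_log2, 0))
  prof <- profile_sample(at_mean, ref, age_group = ">2y", sample_id = "gm")
  expect_identical(nrow(prof), nrow(at_mean))
  expect_true(all(abs(prof$z[!prof$not_detected]) < 2.5))
  expect_true(all(prof$flag[!prof$not_detected] == "normal"))
  # unknown age group errors
  expect_error(profile_sample(at_mean, ref, age_group = "99y"),
               class = "oa_profile_error")
})

test_that("common scaling of cohort and sample leaves z unchanged", {
  set.seed(13)
  vals <- 2^rnorm(30, 4, 0.5)
  f <- 3.7
  ref1 <- build_reference(make_controls(vals), lods = 0.5)
  ref2 <- build_reference(make_controls(f * vals), lods = f * 0.5)
  z1 <- zscore(10, ref1$mean_log2, ref1$sd_log2, ref1$lod_norm)
  z2 <- zscore(f * 10, ref2$mean_log2, ref2$sd_log2, ref2$lod_norm)
  expect_equal(z1, z2)
})

test_that("profile plots render one glyph per analyte", {
  panel <- oa_test_panel()
  spec <- cohort_spec(panel)
  coh <- simulate_cohort(spec, seed = 21)
  ref <- build_reference(coh, spec_lods(spec))
  case <- simulate_case(iem_case_library()$GA1, spec, seed = 5)
  prof <- profile_sample(case, ref)
  p <- ggplot2::autoplot(prof)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_identical(nrow(built$data[[4]]), nrow(prof)) # the point layer
  tmp <- withr::local_tempfile(fileext = ".png")
  render_profile_plot(prof, tmp)
  expect_true(file.exists(tmp))
  # highlighted (non-grey) points equal the flagged analytes
  flagged <- sum(prof$flag != "normal")
  expect_identical(sum(built$data[[4]]$colour != "grey40"), flagged)
})
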