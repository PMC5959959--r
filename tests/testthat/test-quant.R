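# Calibration, quantification modes, LOD/LOQ, precision, normalization,
# batch QC.

test_that("calibration recovers exact lines", {
  cc <- fit_calibration(data.frame(conc = c(0, 10, 20), ratio = c(0, 5, 10)))
  expect_equal(cc$slope, 0.5)
  expect_equal(cc$intercept, 0, tolerance = 1e-12)
  expect_equal(cc$r2, 1)
  conc <- c(0, 5, 10, 20, 40)
  cc2 <- fit_calibration(data.frame(conc = conc, ratio = 0.2 * conc + 0.1))
  expect_equal(cc2$slope, 0.2)
  expect_equal(cc2$intercept, 0.1)
  expect_error(
    fit_calibration(data.frame(conc = c(5, 5, 5), ratio = c(1, 2, 3))),
    class = "oa_calibration_error")
})

test_that("tidy and glance expose the fit in broom layout", {
  cc <- fit_calibration(data.frame(conc = c(0, 10, 20, 30),
                                   ratio = c(0.1, 5, 10.2, 15)),
                        analyte = "Glutaric acid")
  td <- tidy(cc)
  expect_setequal(td$term, c("intercept", "slope"))
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value"))
  gl <- glance(cc)
  expect_identical(gl$analyte, "Glutaric acid")
  expect_true(gl$r.squared > 0.99)
})

test_that("quantification inverts calibration and clips below zero", {
  cc <- fit_calibration(data.frame(conc = c(0, 10, 20), ratio = c(0, 5, 10)))
  q <- quantify(cc, 5)
  expect_equal(q$conc, 10)
  expect_false(q$below_lod)
  q0 <- quantify(cc, 0)
  expect_identical(q0$conc, 0)
  expect_true(q0$below_lod)
  # round trip: any noise-free point on the line is recovered exactly
  pts <- data.frame(conc = c(2, 8, 32, 128), ratio = 0.37 * c(2, 8, 32, 128) + 0.05)
  cc2 <- fit_calibration(pts)
  expect_equal(quantify(cc2, pts$ratio)$conc, pts$conc)
  # dilution enters multiplicatively
  expect_equal(quantify(cc2, pts$ratio[2], dilution_factor = 16)$conc,
               16 * pts$conc[2])
})

test_that("relative-ISTD quantification follows the area-ratio rule", {
  expect_equal(quantify_relative(2000, 1000, 10), 20)
  expect_equal(quantify_relative(0, 1000, 10), 0)
  expect_equal(quantify_relative(500, 500, 25), 25) # equal areas -> ISTD conc
  expect_equal(quantify_relative(2000, 1000, 10, dilution_factor = 16), 320)
  expect_error(quantify_relative(100, 0, 10),
               class = "oa_missing_istd_error")
})

test_that("LOD and LOQ scale noise through the slope", {
  cc <- fit_calibration(data.frame(conc = c(0, 1, 2), ratio = c(0, 10, 20)))
  ll <- estimate_lod_loq(cc, noise = 5)
  expect_equal(ll$lod, 1.5)
  expect_equal(ll$loq, 5)
  expect_equal(estimate_lod_loq(cc, 0)$lod, 0)
  expect_equal(ll$loq / ll$lod, 10 / 3)
})

test_that("precision is the percent coefficient of variation", {
  expect_equal(precision(c(10, 10, 10)), 0)
  expect_equal(precision(c(8, 12)), 100 * sd(c(8, 12)) / 10) # 28.28%
  expect_equal(precision(c(8, 12)), 28.28, tolerance = 1e-3)
  expect_error(precision(c(5)), class = "oa_quant_error")
  expect_error(precision(c(-2, 2)), class = "oa_quant_error")
  # replicates generated at 10% CV land near 10%
  set.seed(9)
  reps <- 10 * (1 + rnorm(20, 0, 0.1))
  cv <- precision(reps)
  expect_gt(cv, 6); expect_lt(cv, 14)
})

test_that("creatinine normalization divides and rejects bad creatinine", {
  expect_equal(normalize_creatinine(100, 1), 100)
  expect_equal(normalize_creatinine(50, 2.5), 20)
  expect_equal(normalize_creatinine(0, 2.5), 0)
  expect_error(normalize_creatinine(10, 0), class = "oa_quant_error")
  expect_error(normalize_creatinine(10, -1), class = "oa_quant_error")
})

test_that("QC placement rule accepts the bracketed design", {
  manifest <- tibble::tibble(
    sample_id = c("qc1", "bl1", sprintf("p%02d", 1:24), "qc2", "bl2"),
    sample_type = c("qc", "blank", rep("patient", 24), "qc", "blank"))
  rep <- check_batch_qc(manifest)
  expect_true(rep$placement_ok)
  expect_true(rep$pass)
})

test_that("QC placement rule flags missing brackets and gaps", {
  no_qc <- tibble::tibble(sample_id = c("p1", "p2"),
                          sample_type = c("patient", "patient"))
  expect_error(check_batch_qc(no_qc), class = "oa_batch_error")
  # 30 samples with a single leading QC pair: gap too large, no closer
  open <- tibble::tibble(
    sample_id = c("qc1", "bl1", sprintf("p%02d", 1:30)),
    sample_type = c("qc", "blank", rep("patient", 30)))
  rep <- check_batch_qc(open)
  expect_false(rep$placement_ok)
})

test_that("QC recovery and carry-over flags respect tolerances", {
  manifest <- tibble::tibble(
    sample_id = c("qc1", "bl1", "p1", "qc2", "bl2"),
    sample_type = c("qc", "blank", "patient", "qc", "blank"))
  qc <- tibble::tibble(
    analyte = c("A", "B", "C"),
    measured = c(100, 50, 118),
    target = c(100, 100, 100),
    blank_area = c(0, 0, 500),
    qc_area = c(1000, 1000, 1000))
  rep <- check_batch_qc(manifest, qc, tolerance_pct = 20)
  flags <- rep$analyte_flags
  expect_identical(flags$recovery_flag, c(FALSE, TRUE, FALSE))
  expect_identical(flags$carryover_flag, c(FALSE, FALSE, TRUE))
  expect_false(rep$pass)
})
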