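# Passing-Bablok regression, recovery/linearity, significance testing.

test_that("Passing-Bablok is exact on affine data", {
  pb <- passing_bablok(1:10, 1:10)
  expect_equal(pb$slope, 1)
  expect_equal(pb$intercept, 0)
  pb2 <- passing_bablok(1:10, 2 * (1:10) + 1)
  expect_equal(pb2$slope, 2)
  expect_equal(pb2$intercept, 1)
  expect_error(passing_bablok(1:2, 1:2), class = "oa_pb_error")
  expect_error(passing_bablok(c(1, 1, 1), 1:3), class = "oa_pb_error")
})

test_that("estimator equals the exhaustive pairwise-slope oracle", {
  set.seed(101)
  for (k in 1:100) {
    n <- sample(5:30, 1)
    x <- round(runif(n, 1, 50), 2)
    y <- round(0.9 * x + rnorm(n, 0, 3), 2)
    expect_identical(passing_bablok(x, y)$slope, pb_oracle_slope(x, y))
  }
})

test_that("Passing-Bablok handles negatively correlated data with the K offset", {
  set.seed(55)
  for (k in 1:25) {
    n <- sample(5:15, 1)
    x <- runif(n, 1, 20)
    y <- -2 * x + 50 + rnorm(n, 0, 1)   # many pairwise slopes below -1
    expect_identical(passing_bablok(x, y)$slope, pb_oracle_slope(x, y))
  }
})

test_that("Passing-Bablok is scale-invariant and near-symmetric", {
  set.seed(7)
  x <- runif(15, 5, 80)
  y <- x + rnorm(15, 0, 4)
  pb <- passing_bablok(x, y)
  pb_scaled <- passing_bablok(10 * x, 10 * y)
  expect_equal(pb_scaled$slope, pb$slope)
  expect_equal(pb_scaled$intercept, 10 * pb$intercept)
  pb_swap <- passing_bablok(y, x)
  expect_equal(pb_swap$slope, 1 / pb$slope, tolerance = 0.15)
  td <- tidy(pb)
  expect_identical(td$term, c("slope", "intercept"))
  expect_true(td$conf.low[1] <= pb$slope && pb$slope <= td$conf.high[1])
})

test_that("slope confidence interval covers 1 for equivalent methods", {
  set.seed(42)
  hits <- replicate(200, {
    x <- runif(20, 1, 100)
    y <- x + rnorm(20, 0, 5)
    ci <- passing_bablok(x, y)$slope_ci
    ci[1] <= 1 && 1 <= ci[2]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("recovery is the regression slope on spiked amounts", {
  d <- tibble::tibble(spiked = c(0, 10, 20, 40), measured = c(0, 10, 20, 40))
  r <- assess_recovery_linearity(d)
  expect_equal(r$recovery, 100)
  expect_equal(r$r2, 1)
  expect_true(r$recovery_acceptable)
  d$measured <- 0.9 * d$spiked
  r <- assess_recovery_linearity(d)
  expect_equal(r$recovery, 90)
  expect_true(r$recovery_acceptable)
  d$measured <- 0.5 * d$spiked
  r <- assess_recovery_linearity(d)
  expect_equal(r$recovery, 50)
  expect_false(r$recovery_acceptable)
  # ratio variant
  r2 <- assess_recovery_linearity(
    tibble::tibble(spiked = c(10, 20), measured = c(11, 22)),
    method = "ratio")
  expect_equal(r2$recovery, 110)
  expect_error(
    assess_recovery_linearity(tibble::tibble(spiked = 0, measured = 1)),
    class = "oa_recovery_error")
})

test_that("test choice follows normality screening", {
  set.seed(3)
  a <- rnorm(20, 10, 1)
  b <- rnorm(20, 10, 1)
  res <- significance_test(a, b)
  expect_identical(res$test_used, "t")
  # identical lists carry no evidence of a difference
  v <- rnorm(10, 10)
  res_id <- significance_test(v, v)
  expect_identical(res_id$test_used, "t")
  expect_gte(res_id$p_value, 0.99)
  # fully tied degenerate groups fall to the rank test with p = 1
  res2 <- significance_test(rep(5, 10), rep(5, 10))
  expect_identical(res2$test_used, "mann_whitney")
  expect_gte(res2$p_value, 0.99)
  # strongly skewed data triggers the rank test
  res3 <- significance_test(exp(rnorm(30, 0, 1.5)), exp(rnorm(30, 0, 1.5)))
  expect_identical(res3$test_used, "mann_whitney")
  expect_error(significance_test(1:2, 1:5), class = "oa_test_error")
})

test_that("type-I error and power are in the expected ranges", {
  set.seed(12)
  p_null <- replicate(200, {
    significance_test(rnorm(20), rnorm(20))$p_value
  })
  # ~95% of null replicates should not reject at 0.05
  expect_gte(mean(p_null > 0.05), 0.9)
  p_shift <- replicate(100, {
    significance_test(rnorm(20), rnorm(20, 3))$p_value  # 3 sigma shift
  })
  expect_gte(mean(p_shift < 0.05), 0.99)
})

test_that("per-analyte comparison report carries flags by construction", {
  set.seed(31)
  paired <- purrr::map_dfr(c(good = 1.0, biased = 1.5), function(sl) {
    x <- runif(12, 5, 80)
    tibble::tibble(conc_ref = x, conc_test = sl * x + rnorm(12, 0, 1),
                   spiked = x)
  }, .id = "analyte")
  rep <- compare_methods(paired)
  expect_identical(nrow(rep), 2L)
  good <- rep[rep$analyte == "good", ]
  expect_true(good$slope_in_range)
  expect_true(good$recovery_acceptable)
  biased <- rep[rep$analyte == "biased", ]
  expect_false(biased$slope_in_range)
  expect_false(biased$recovery_acceptable)
  expect_identical(biased$recovery_acceptable,
                   biased$recovery >= 80 & biased$recovery <= 120)
  expect_true(all(rep$pb_slope_lo <= rep$pb_slope &
                    rep$pb_slope <= rep$pb_slope_hi))
})
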