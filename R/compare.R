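# Method cross-validation: Passing-Bablok regression, spiked recovery and
# linearity, per-analyte significance testing.

#' Passing-Bablok regression
#'
#' Non-parametric, symmetric regression for method comparison (classic
#' 1983 estimator). All pairwise slopes `S_ij = (y_j - y_i)/(x_j - x_i)`
#' over `i < j` with `x_i != x_j` are formed, slopes exactly equal to -1
#' are excluded, and the slope estimate is the shifted median of the
#' sorted slopes with offset `K`, the number of slopes below -1 (this
#' makes the estimator invariant to swapping x and y). The intercept is
#' `median(y - slope * x)`. Confidence limits come from the rank-based
#' normal approximation; intercept limits re-use the slope limits.
#'
#' @param x Reference-method concentrations.
#' @param y Test-method concentrations.
#' @param conf_level Two-sided confidence level for the slope (default
#'   0.95).
#' @return An object of class `oa_pb`: `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci`, `n`, `n_slopes`, `data`. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @references Passing, H. and Bablok, W. (1983). A new biometrical
#'   procedure for testing the equality of measurements from two
#'   different analytical methods. J Clin Chem Clin Biochem 21, 709-720.
#' @examples
#' passing_bablok(1:10, 2 * (1:10) + 1)
#' @export
passing_bablok <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort("Passing-Bablok needs >= 3 paired observations",
          class = "oa_pb_error")
  }
  if (length(unique(x)) < 2) {
    abort("Passing-Bablok needs variation in x", class = "oa_pb_error")
  }
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  s <- dy[dx != 0] / dx[dx != 0]
  s <- s[s != -1]
  s <- sort(s)
  N <- length(s)
  if (N < 1) abort("no valid pairwise slopes", class = "oa_pb_error")
  K <- sum(s < -1)
  shifted_median <- function(sorted, offset) {
    m <- length(sorted)
    if (m %% 2 == 1) {
      sorted[(m + 1) / 2 + offset]
    } else {
      (sorted[m / 2 + offset] + sorted[m / 2 + 1 + offset]) / 2
    }
  }
  slope <- shifted_median(s, K)
  # rank-based normal-approximation CI (Passing & Bablok 1983, eq. for w)
  w <- qnorm(1 - (1 - conf_level) / 2) *
    sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- max(1L, as.integer(round((N - w) / 2)))
  m2 <- min(N, N - m1 + 1L)
  lo <- s[min(N, max(1L, m1 + K))]
  hi <- s[min(N, max(1L, m2 + K))]
  intercept <- median(y - slope * x)
  int_lo <- median(y - hi * x)
  int_hi <- median(y - lo * x)
  structure(list(
    slope = slope, intercept = intercept,
    slope_ci = c(lo, hi), intercept_ci = c(int_lo, int_hi),
    n = n, n_slopes = N, conf_level = conf_level,
    data = tibble::tibble(x = x, y = y)
  ), class = "oa_pb")
}

#' @export
print.oa_pb <- function(x, ...) {
  cat(sprintf(
    "<oa_pb> slope %.4f [%.4f, %.4f], intercept %.4f [%.4f, %.4f], n = %d\n",
    x$slope, x$slope_ci[1], x$slope_ci[2],
    x$intercept, x$intercept_ci[1], x$intercept_ci[2], x$n))
  invisible(x)
}

#' @method tidy oa_pb
#' @export
tidy.oa_pb <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    conf.low = c(x$slope_ci[1], x$intercept_ci[1]),
    conf.high = c(x$slope_ci[2], x$intercept_ci[2])
  )
}

#' @method glance oa_pb
#' @export
glance.oa_pb <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 slope.conf.low = x$slope_ci[1],
                 slope.conf.high = x$slope_ci[2],
                 n = x$n, conf.level = x$conf_level)
}

#' Spiked recovery and linearity
#'
#' Default (`method = "regression"`): recovery is 100 times the
#' ordinary-least-squares slope of the measured result on the weighed-in
#' (spiked) amount, with the coefficient of determination of the same fit
#' as the linearity metric -- the design used in external quality-assurance
#' schemes with graded spike levels. `method = "ratio"` instead averages
#' the simple percentage ratios measured/spiked. The clinical acceptance
#' band is a recovery between 80 and 120%.
#'
#' @param data Tibble with columns `spiked` and `measured` (umol/L) for
#'   one analyte.
#' @param method `"regression"` (default) or `"ratio"`.
#' @param band Acceptance band for recovery, percent.
#' @return One-row tibble: `recovery`, `recovery_acceptable`, `slope`,
#'   `intercept`, `r2`, `n`, `method`.
#' @export
assess_recovery_linearity <- function(data, method = c("regression", "ratio"),
                                      band = c(80, 120)) {
  method <- match.arg(method)
  stopifnot(all(c("spiked", "measured") %in% names(data)))
  data <- data[is.finite(data$spiked) & is.finite(data$measured), ]
  if (nrow(data) == 0 || all(data$spiked == 0)) {
    abort("recovery undefined without spiked levels", class = "oa_recovery_error")
  }
  if (method == "regression") {
    if (dplyr::n_distinct(data$spiked) < 3) {
      abort("linearity needs >= 3 distinct spike levels",
            class = "oa_recovery_error")
    }
    fit <- lm(measured ~ spiked, data = data)
    slope <- unname(coef(fit)[["spiked"]])
    recovery <- 100 * slope
    out <- tibble::tibble(
      recovery = recovery,
      recovery_acceptable = recovery >= band[1] & recovery <= band[2],
      slope = slope,
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r2 = suppressWarnings(summary(fit)$r.squared),
      n = nrow(data), method = method)
  } else {
    pos <- data[data$spiked > 0, ]
    recovery <- mean(100 * pos$measured / pos$spiked)
    out <- tibble::tibble(
      recovery = recovery,
      recovery_acceptable = recovery >= band[1] & recovery <= band[2],
      slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
      n = nrow(pos), method = method)
  }
  out
}

#' Two-group significance test with normality-based test choice
#'
#' Shapiro-Wilk normality tests on both groups decide the test: when both
#' are consistent with normality (p > `alpha_normality`) a Welch t-test is
#' used, otherwise a two-sided Mann-Whitney U test.
#'
#' @param a,b Numeric vectors (each n >= 3).
#' @param alpha_normality Significance level of the Shapiro-Wilk screens.
#' @return One-row tibble: `p_value`, `test_used` (`"t"` or
#'   `"mann_whitney"`), `statistic`.
#' @export
significance_test <- function(a, b, alpha_normality = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    abort("significance test needs >= 3 values per group",
          class = "oa_test_error")
  }
  normal <- function(v) {
    if (sd(v) == 0) return(FALSE)  # degenerate; rank test handles ties
    shapiro.test(v)$p.value > alpha_normality
  }
  if (normal(a) && normal(b)) {
    ht <- t.test(a, b)
    tibble::tibble(p_value = ht$p.value, test_used = "t",
                   statistic = unname(ht$statistic))
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    p <- ht$p.value
    if (is.nan(p)) p <- 1  # fully tied groups carry no evidence
    tibble::tibble(p_value = p, test_used = "mann_whitney",
                   statistic = unname(ht$statistic))
  }
}

#' Per-analyte method comparison report
#'
#' For each analyte in a paired test/reference concentration table,
#' computes spiked recovery and linearity (when spike levels are present),
#' Passing-Bablok slope and intercept with confidence limits, and a
#' significance test of the method difference. Flags follow the clinical
#' conventions: recovery acceptable in 80-120%, Passing-Bablok slope in
#' range 0.8-1.2.
#'
#' @param paired Tibble with columns `analyte`, `conc_test`, `conc_ref`
#'   and optionally `spiked` (umol/L).
#' @param conf_level Confidence level for the Passing-Bablok limits.
#' @return Tibble of class `oa_comparison`, one row per analyte:
#'   recovery and linearity columns, `pb_slope`, `pb_slope_lo`,
#'   `pb_slope_hi`, `pb_intercept`, `slope_in_range`, `p_value`,
#'   `test_used`.
#' @export
compare_methods <- function(paired, conf_level = 0.95) {
  stopifnot(all(c("analyte", "conc_test", "conc_ref") %in% names(paired)))
  out <- paired |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(function(d, key) {
      pb <- passing_bablok(d$conc_ref, d$conc_test, conf_level)
      sig <- significance_test(d$conc_test, d$conc_ref)
      rec <- if ("spiked" %in% names(d) && any(is.finite(d$spiked)) &&
                 dplyr::n_distinct(d$spiked[is.finite(d$spiked)]) >= 3) {
        assess_recovery_linearity(
          tibble::tibble(spiked = d$spiked, measured = d$conc_test))
      } else {
        tibble::tibble(recovery = NA_real_, recovery_acceptable = NA,
                       slope = NA_real_, intercept = NA_real_,
                       r2 = NA_real_, n = nrow(d), method = NA_character_)
      }
      tibble::tibble(
        n = nrow(d),
        recovery = rec$recovery,
        recovery_acceptable = rec$recovery_acceptable,
        lin_slope = rec$slope, lin_r2 = rec$r2,
        pb_slope = pb$slope, pb_slope_lo = pb$slope_ci[1],
        pb_slope_hi = pb$slope_ci[2], pb_intercept = pb$intercept,
        slope_in_range = pb$slope >= 0.8 & pb$slope <= 1.2,
        p_value = sig$p_value, test_used = sig$test_used)
    }) |>
    dplyr::ungroup()
  class(out) <- c("oa_comparison", class(out))
  out
}
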