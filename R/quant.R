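# Calibration fitting, sample quantification, LOD/LOQ, precision,
# creatinine normalization, batch QC.

#' Fit a per-analyte calibration curve
#'
#' Ordinary least-squares line of response ratio (analyte peak area over
#' internal-standard peak area) versus nominal concentration, one curve per
#' analyte. Unweighted by default; `weighting = "1/x"` weights each point
#' by the reciprocal of its concentration (zero-concentration points get
#' the largest finite weight present).
#'
#' @param data Data frame with columns `conc` (umol/L) and `ratio`
#'   (unitless response ratio).
#' @param analyte Optional analyte name carried in the result.
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return An object of class `oa_calibration` with elements `analyte`,
#'   `slope` (ratio per umol/L), `intercept`, `r2`, `n`, `points` and the
#'   underlying `lm` fit. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' fit_calibration(data.frame(conc = c(0, 10, 20), ratio = c(0, 5, 10)))
#' @export
fit_calibration <- function(data, analyte = NA_character_,
                            weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("conc", "ratio") %in% names(data)))
  data <- tibble::as_tibble(data[c("conc", "ratio")])
  if (dplyr::n_distinct(data$conc) < 2) {
    abort("calibration needs >= 2 distinct concentration levels",
          class = "oa_calibration_error")
  }
  w <- NULL
  if (weighting == "1/x") {
    w <- 1 / data$conc
    if (any(!is.finite(w))) w[!is.finite(w)] <- max(w[is.finite(w)])
  }
  fit <- lm(ratio ~ conc, data = data, weights = w)
  structure(list(
    analyte = analyte,
    slope = unname(coef(fit)[["conc"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    r2 = suppressWarnings(summary(fit)$r.squared),
    n = nrow(data),
    weighting = weighting,
    points = data,
    fit = fit
  ), class = "oa_calibration")
}

#' @export
print.oa_calibration <- function(x, ...) {
  cat(sprintf(
    "<oa_calibration>%s slope %.4g, intercept %.4g, R2 %.4f (n = %d%s)\n",
    if (is.na(x$analyte)) "" else paste0(" ", x$analyte),
    x$slope, x$intercept, x$r2, x$n,
    if (x$weighting == "none") "" else ", 1/x weighted"))
  invisible(x)
}

#' @method tidy oa_calibration
#' @export
tidy.oa_calibration <- function(x, ...) {
  out <- tibble::as_tibble(summary(x$fit)$coefficients, rownames = "term")
  names(out) <- c("term", "estimate", "std.error", "statistic", "p.value")
  out$term[out$term == "conc"] <- "slope"
  out$term[out$term == "(Intercept)"] <- "intercept"
  out
}

#' @method glance oa_calibration
#' @export
glance.oa_calibration <- function(x, ...) {
  tibble::tibble(analyte = x$analyte, slope = x$slope,
                 intercept = x$intercept, r.squared = x$r2, n = x$n,
                 weighting = x$weighting)
}

#' Back-calculate concentration from a calibration curve
#'
#' Inverts the calibration line and applies the sample dilution factor:
#' `conc = (ratio - intercept) / slope * dilution_factor`. Negative
#' back-calculated concentrations are clipped to 0 and flagged
#' `below_lod`; downstream reference building imputes them at the LOD.
#'
#' @param curve An `oa_calibration`.
#' @param ratio Numeric vector of response ratios.
#' @param dilution_factor Per-sample dilution factor (>= 1 for diluted
#'   urine; scalar or vector).
#' @return Tibble with `conc` (umol/L) and `below_lod`.
#' @export
quantify <- function(curve, ratio, dilution_factor = 1) {
  stopifnot(inherits(curve, "oa_calibration"))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    abort("calibration slope must be > 0 to quantify",
          class = "oa_quant_error")
  }
  conc <- (ratio - curve$intercept) / curve$slope * dilution_factor
  # picomolar epsilon absorbs floating-point residue from exact-line fits
  below <- conc <= 1e-9
  tibble::tibble(conc = ifelse(below, 0, conc), below_lod = below)
}

#' Quantify by the relative internal-standard method
#'
#' For surrogate-standard analytes (no authentic calibrant available) and
#' the medication markers, concentration is the analyte/ISTD area ratio
#' times the spiked ISTD concentration, assuming the analyte has the same
#' response factor as its internal standard.
#'
#' @param analyte_area,istd_area Peak areas (counts x min).
#' @param istd_conc Spiked ISTD concentration, umol/L.
#' @param dilution_factor Per-sample dilution factor.
#' @return Concentration in umol/L (vectorized).
#' @examples
#' quantify_relative(2000, 1000, 10) # 20 umol/L
#' @export
quantify_relative <- function(analyte_area, istd_area, istd_conc,
                              dilution_factor = 1) {
  if (any(istd_area <= 0)) {
    abort("ISTD peak area is zero: failed injection or missing spike",
          class = "oa_missing_istd_error")
  }
  analyte_area / istd_area * istd_conc * dilution_factor
}

#' Limits of detection and quantification
#'
#' Converts a response-scale noise level into concentration units through
#' the calibration slope: the LOD is the concentration at which the
#' signal-to-noise ratio reaches 3, and the LOQ the concentration at
#' S/N = 10, so `lod = 3 * noise / slope` and `loq = 10 * noise / slope`.
#'
#' @param curve An `oa_calibration`.
#' @param noise Standard deviation of the blank-level response ratio.
#' @return Tibble with `lod` and `loq` in umol/L.
#' @export
estimate_lod_loq <- function(curve, noise) {
  stopifnot(inherits(curve, "oa_calibration"), noise >= 0)
  if (curve$slope <= 0) {
    abort("calibration slope must be > 0", class = "oa_quant_error")
  }
  tibble::tibble(lod = 3 * noise / curve$slope,
                 loq = 10 * noise / curve$slope)
}

#' Coefficient of variation of replicate measurements
#'
#' `100 * sd / mean` over replicate concentrations, the within- and
#' between-run precision metric.
#'
#' @param values Numeric vector of replicate concentrations (n >= 2,
#'   positive mean).
#' @return CV in percent.
#' @export
precision <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort("precision needs >= 2 replicates", class = "oa_quant_error")
  }
  m <- mean(values)
  if (m <= 0) {
    abort("CV undefined for non-positive mean", class = "oa_quant_error")
  }
  100 * sd(values) / m
}

#' Normalize a urinary concentration to creatinine
#'
#' Divides the analyte concentration (umol/L) by the urinary creatinine
#' concentration (mmol/L) to correct for urine dilution, giving
#' umol analyte per mmol creatinine. Creatinine is an external laboratory
#' input (clinical-chemistry assay).
#'
#' @param conc Analyte concentration, umol/L.
#' @param creatinine Urinary creatinine, mmol/L (> 0).
#' @return Normalized concentration, umol/mmol.
#' @export
normalize_creatinine <- function(conc, creatinine) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0)) {
    abort("creatinine must be > 0 mmol/L; sample is unreportable otherwise",
          class = "oa_quant_error")
  }
  conc / creatinine
}

#' Check batch quality-control placement and recovery
#'
#' Verifies the batch design rule that a QC sample and a blank are injected
#' at the start of the sequence and again after every block of at most
#' `max_gap` study samples (default 24), with a closing QC/blank pair after
#' the final block. Optionally checks per-analyte QC recovery against
#' targets and blank carry-over against a fraction of the QC signal.
#'
#' @param manifest Tibble describing the injection sequence in order, with
#'   columns `sample_id` and `sample_type` (one of `"calibrant"`, `"qc"`,
#'   `"blank"`, `"patient"`).
#' @param qc_measured Optional tibble with `analyte`, `measured`, `target`
#'   (concentrations) and optionally `blank_area`, `qc_area`.
#' @param tolerance_pct Allowed QC recovery deviation from 100%, percent.
#' @param max_gap Maximum number of study samples between QC injections.
#' @param blank_fraction Blank area above this fraction of the QC area is
#'   flagged as carry-over.
#' @return A list of class `oa_qc_report`: `placement_ok`, `placement`
#'   (per-rule detail), `analyte_flags` (or `NULL`), `pass`.
#' @export
check_batch_qc <- function(manifest, qc_measured = NULL, tolerance_pct = 20,
                           max_gap = 24, blank_fraction = 0.05) {
  stopifnot(all(c("sample_id", "sample_type") %in% names(manifest)))
  types <- manifest$sample_type
  if (!any(types == "qc")) {
    abort("batch contains no QC injection", class = "oa_batch_error")
  }
  study <- types %in% c("patient")
  qc_pos <- which(types == "qc")
  blank_pos <- which(types == "blank")
  starts_with_pair <- length(qc_pos) > 0 && length(blank_pos) > 0 &&
    min(qc_pos) < min(which(study), Inf) &&
    min(blank_pos) < min(which(study), Inf)
  # count study samples in the gaps between consecutive QC injections
  gaps <- integer(0)
  bounds <- c(qc_pos, nrow(manifest) + 1L)
  for (k in seq_len(length(qc_pos))) {
    lo <- qc_pos[k]
    hi <- bounds[k + 1]
    gaps <- c(gaps, sum(study[seq(lo, hi - 1)]))
  }
  trailing <- if (any(study)) max(which(study)) < max(qc_pos) else TRUE
  gap_ok <- all(gaps <= max_gap)
  placement <- tibble::tibble(
    rule = c("qc and blank before first study sample",
             sprintf("<= %d study samples between QC injections", max_gap),
             "closing QC after the last study sample"),
    pass = c(starts_with_pair, gap_ok, trailing)
  )
  flags <- NULL
  if (!is.null(qc_measured)) {
    flags <- qc_measured |>
      dplyr::mutate(
        recovery = 100 * .data$measured / .data$target,
        recovery_flag = abs(.data$recovery - 100) > tolerance_pct
      )
    if (all(c("blank_area", "qc_area") %in% names(qc_measured))) {
      flags <- dplyr::mutate(
        flags,
        carryover_flag = !is.na(.data$blank_area) & !is.na(.data$qc_area) &
          .data$blank_area > blank_fraction * .data$qc_area)
    }
  }
  structure(list(
    placement_ok = all(placement$pass),
    placement = placement,
    analyte_flags = flags,
    pass = all(placement$pass) &&
      (is.null(flags) || !any(flags$recovery_flag, na.rm = TRUE))
  ), class = "oa_qc_report")
}

#' @export
print.oa_qc_report <- function(x, ...) {
  cat(sprintf("<oa_qc_report> placement %s, overall %s\n",
              if (x$placement_ok) "OK" else "FAILED",
              if (x$pass) "PASS" else "FAIL"))
  print(x$placement)
  if (!is.null(x$analyte_flags) && any(x$analyte_flags$recovery_flag)) {
    cat("flagged analytes:\n")
    print(dplyr::filter(x$analyte_flags, .data$recovery_flag))
  }
  invisible(x)
}
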