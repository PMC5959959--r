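# Batch-level bridge: peak lists -> measurements -> response ratios ->
# calibration -> creatinine-normalized sample quantifications.

#' Response ratios from per-sample measurements
#'
#' Joins each analyte's peak area to its internal standard's area within
#' the same injection to give the response ratio used for quantification.
#'
#' @param measurements Tibble from [measure_sample()] (optionally
#'   row-bound over samples with a `sample_id` column).
#' @param panel An `oa_panel`.
#' @return Tibble with one row per sample x analyte: `area`, `istd_area`,
#'   `ratio`, `found`, `ambiguous`.
#' @export
response_ratios <- function(measurements, panel) {
  stopifnot(inherits(panel, "oa_panel"))
  if (!"sample_id" %in% names(measurements)) {
    measurements$sample_id <- "sample"
  }
  analyte <- dplyr::filter(measurements, .data$kind == "analyte")
  istd <- measurements |>
    dplyr::filter(.data$kind == "istd") |>
    dplyr::select("sample_id", istd_name = "name", istd_area = "area")
  analyte |>
    dplyr::left_join(
      dplyr::select(panel$entries, name = "name", "istd_name"),
      by = "name") |>
    dplyr::left_join(istd, by = c("sample_id", "istd_name")) |>
    dplyr::transmute(
      sample_id = .data$sample_id, analyte = .data$name,
      area = .data$area, istd_area = .data$istd_area,
      ratio = dplyr::if_else(.data$istd_area > 0,
                             .data$area / .data$istd_area, NA_real_),
      found = .data$found, ambiguous = .data$ambiguous)
}

#' Fit calibration curves for a whole batch
#'
#' @param cal_ratios Response ratios of the calibrant injections (from
#'   [response_ratios()]).
#' @param levels Tibble with `sample_id`, `analyte`, `conc_injected`
#'   giving the nominal level of each calibrant injection (e.g. from
#'   [calibrant_truths()]).
#' @param weighting Passed to [fit_calibration()].
#' @return Tibble with one row per analyte: `slope`, `intercept`, `r2`,
#'   `n` and a `curve` list-column of `oa_calibration` objects.
#' @export
calibrate_batch <- function(cal_ratios, levels, weighting = "none") {
  pts <- cal_ratios |>
    dplyr::inner_join(
      dplyr::select(levels, "sample_id", "analyte", conc = "conc_injected"),
      by = c("sample_id", "analyte"))
  pts |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(function(d, key) {
      curve <- fit_calibration(d[c("conc", "ratio")],
                               analyte = key$analyte[[1]],
                               weighting = weighting)
      tibble::tibble(slope = curve$slope, intercept = curve$intercept,
                     r2 = curve$r2, n = curve$n, curve = list(curve))
    }) |>
    dplyr::ungroup()
}

#' Quantify a batch of samples against fitted curves
#'
#' Externally calibrated analytes are back-calculated through their
#' calibration curves; surrogate-standard and medication analytes use the
#' relative internal-standard rule. Concentrations are scaled by the
#' per-sample dilution factor and normalized to creatinine where a
#' creatinine value is available.
#'
#' @param ratios Response ratios of the study samples.
#' @param curves Output of [calibrate_batch()].
#' @param panel An `oa_panel`.
#' @param manifest Tibble with `sample_id`, `dilution_factor` and
#'   `creatinine` (mmol/L; `NA` skips normalization).
#' @return Tibble with one row per sample x analyte: `conc` (umol/L
#'   urine), `conc_norm` (umol/mmol creatinine), `below_lod`,
#'   `ambiguous`.
#' @export
quantify_batch <- function(ratios, curves, panel, manifest) {
  stopifnot(inherits(panel, "oa_panel"))
  mode <- dplyr::select(panel$entries, analyte = "name", "quant_mode",
                        "istd_name")
  istd_levels <- dplyr::select(panel$istds, istd_name = "name",
                               istd_conc = "conc")
  curve_map <- setNames(curves$curve, curves$analyte)
  out <- ratios |>
    dplyr::left_join(mode, by = "analyte") |>
    dplyr::left_join(istd_levels, by = "istd_name") |>
    dplyr::left_join(
      dplyr::select(manifest, "sample_id", "dilution_factor", "creatinine"),
      by = "sample_id")
  quant_row <- function(analyte, ratio, area, istd_area, quant_mode,
                        istd_conc, dilution_factor, found) {
    if (quant_mode == "external_calibration") {
      curve <- curve_map[[analyte]]
      if (is.null(curve) || is.na(ratio)) {
        return(tibble::tibble(conc = NA_real_, below_lod = NA))
      }
      q <- quantify(curve, ratio, dilution_factor)
      q$below_lod <- q$below_lod | !found
      if (!found) q$conc <- 0
      q
    } else {
      conc <- if (found && !is.na(istd_area) && istd_area > 0) {
        quantify_relative(area, istd_area, istd_conc, dilution_factor)
      } else {
        0
      }
      tibble::tibble(conc = conc, below_lod = !found)
    }
  }
  q <- purrr::pmap_dfr(
    out[c("analyte", "ratio", "area", "istd_area", "quant_mode",
          "istd_conc", "dilution_factor", "found")],
    quant_row)
  dplyr::bind_cols(out, q) |>
    dplyr::mutate(
      conc_norm = dplyr::if_else(
        !is.na(.data$creatinine) & .data$creatinine > 0,
        .data$conc / .data$creatinine, NA_real_)) |>
    dplyr::select("sample_id", "analyte", "area", "istd_area", "ratio",
                  "conc", "conc_norm", "below_lod", "ambiguous")
}

#' Run the full batch pipeline on rendered peak lists
#'
#' Measures every injection, fits per-analyte calibration curves from the
#' calibrant injections, and quantifies the remaining injections,
#' returning measurements, curves and creatinine-normalized sample
#' quantifications.
#'
#' @param peaklists Named list of peak-list tibbles (one per injection).
#' @param manifest Injection manifest: `sample_id`, `sample_type`,
#'   `dilution_factor`, `creatinine`.
#' @param panel An `oa_panel`.
#' @param cal_levels Calibrant nominal levels (see [calibrate_batch()]).
#' @param mz_tol_ppm,rt_window Extraction and integration settings.
#' @return List with `measurements`, `ratios`, `curves`, `quants`.
#' @export
process_batch <- function(peaklists, manifest, panel, cal_levels,
                          mz_tol_ppm = 10, rt_window = 0.5) {
  measurements <- purrr::imap_dfr(peaklists, function(pk, sid) {
    dplyr::mutate(measure_sample(pk, panel, mz_tol_ppm, rt_window),
                  sample_id = sid, .before = 1)
  })
  ratios <- response_ratios(measurements, panel)
  cal_ids <- manifest$sample_id[manifest$sample_type == "calibrant"]
  curves <- calibrate_batch(
    dplyr::filter(ratios, .data$sample_id %in% cal_ids), cal_levels)
  study <- dplyr::filter(ratios, !.data$sample_id %in% cal_ids)
  quants <- quantify_batch(study, curves, panel, manifest)
  list(measurements = measurements, ratios = ratios, curves = curves,
       quants = quants)
}
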