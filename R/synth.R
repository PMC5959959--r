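# Synthetic data: control cohorts, IEM cases, instrument-level peak lists
# and calibration batches, so the whole pipeline runs offline.

#' Specify a synthetic control cohort
#'
#' Control urinary organic-acid levels are modelled log-normally on the
#' log2 scale, per analyte and age group, on the creatinine-normalized
#' scale (umol/mmol). Defaults place the control geometric mean of each
#' calibrated analyte at twice its lower calibration limit with a log2-SD
#' of 0.5, shift the infant group (0-2y) up 1.5-fold (infants excrete more
#' organic acid per creatinine), and set the LOD at a quarter of the lower
#' calibration limit. Medication markers and the two disease markers seen
#' only in affected patients (hawkinsin, 2-pyrroloylglycine) are absent
#' from control urine, which exercises the never-detected reference rule.
#'
#' @param panel An `oa_panel`.
#' @param n_per_group Named integer vector of cohort sizes per age group.
#' @param sd_log2 Within-group log2 standard deviation of analyte levels.
#' @param infant_fold Multiplicative shift of the 0-2y geometric means.
#' @param creatinine_meanlog,creatinine_sdlog Log-normal parameters of the
#'   urinary creatinine distribution (mmol/L).
#' @return Object of class `oa_cohort_spec`: tibble `analytes` (analyte,
#'   age_group, present, mean_log2, sd_log2, lod_norm) plus cohort sizes
#'   and the creatinine model.
#' @export
cohort_spec <- function(panel,
                        n_per_group = c("0-2y" = 46, ">2y" = 46),
                        sd_log2 = 0.5,
                        infant_fold = 1.5,
                        creatinine_meanlog = log(5),
                        creatinine_sdlog = 0.4) {
  stopifnot(inherits(panel, "oa_panel"), sd_log2 > 0, all(n_per_group >= 2))
  absent <- c("Hawkinsin", "2-Pyrroloylglycine",
              panel$entries$name[panel$entries$category == "medication"])
  base <- panel$entries |>
    dplyr::transmute(
      analyte = .data$name,
      present = !.data$name %in% absent,
      gm = dplyr::if_else(is.na(.data$calib_low), 5, 2 * .data$calib_low),
      lod_norm = dplyr::if_else(is.na(.data$calib_low), 0.5,
                                .data$calib_low / 4)
    )
  analytes <- tidyr::crossing(base,
                              age_group = names(n_per_group)) |>
    dplyr::mutate(
      mean_log2 = log2(.data$gm) +
        dplyr::if_else(.data$age_group == "0-2y", log2(infant_fold), 0),
      sd_log2 = sd_log2
    ) |>
    dplyr::select("analyte", "age_group", "present", "mean_log2",
                  "sd_log2", "lod_norm")
  structure(list(analytes = analytes, n_per_group = n_per_group,
                 creatinine_meanlog = creatinine_meanlog,
                 creatinine_sdlog = creatinine_sdlog),
            class = "oa_cohort_spec")
}

#' LODs declared by a cohort specification
#'
#' @param spec An `oa_cohort_spec`.
#' @return Tibble with `analyte` and `lod_norm` (umol/mmol), suitable for
#'   [build_reference()].
#' @export
spec_lods <- function(spec) {
  stopifnot(inherits(spec, "oa_cohort_spec"))
  dplyr::distinct(spec$analytes, .data$analyte, .data$lod_norm)
}

#' Simulate a control cohort
#'
#' Draws `n_per_group` control samples per age group from the cohort
#' model: per-analyte log2-normal concentrations (absent analytes are 0),
#' flagged `below_lod` when under the analyte LOD, plus a log-normal
#' urinary creatinine. Deterministic for a fixed seed; the RNG state of
#' the caller is untouched.
#'
#' @param spec An `oa_cohort_spec`.
#' @param seed Integer seed.
#' @param prefix Sample-identifier prefix.
#' @return Tibble with `sample_id`, `age_group`, `creatinine`, `analyte`,
#'   `conc_norm`, `below_lod`; the generating spec is attached as
#'   attribute `"spec"`.
#' @export
simulate_cohort <- function(spec, seed = 1, prefix = "ctrl") {
  stopifnot(inherits(spec, "oa_cohort_spec"))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  out <- purrr::imap_dfr(spec$n_per_group, function(n, grp) {
    params <- dplyr::filter(spec$analytes, .data$age_group == grp)
    purrr::map_dfr(seq_len(n), function(i) {
      creat <- exp(rnorm(1, spec$creatinine_meanlog, spec$creatinine_sdlog))
      draw <- ifelse(params$present,
                     2^rnorm(nrow(params), params$mean_log2, params$sd_log2),
                     0)
      tibble::tibble(
        sample_id = sprintf("%s_%s_%02d", prefix, gsub("[^0-9a-zA-Z]", "",
                                                       grp), i),
        age_group = grp,
        creatinine = creat,
        analyte = params$analyte,
        conc_norm = draw,
        below_lod = draw < params$lod_norm
      )
    })
  })
  attr(out, "spec") <- spec
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Specify a synthetic patient case
#'
#' A case is a control draw with designated biomarkers multiplied by
#' fold-changes over the control geometric mean (or over the LOD, for
#' analytes absent from control urine), optionally with medication
#' markers present.
#'
#' @param disease Disease label.
#' @param biomarkers Named numeric vector: analyte name -> fold-change
#'   (> 0).
#' @param medication Character vector of medication-marker analytes to
#'   inject.
#' @param medication_level Medication-marker level as a multiple of the
#'   marker LOD.
#' @return Object of class `oa_case_spec`.
#' @export
case_spec <- function(disease, biomarkers, medication = character(),
                      medication_level = 50) {
  stopifnot(is.numeric(biomarkers), length(names(biomarkers)) ==
              length(biomarkers), all(biomarkers > 0))
  structure(list(disease = disease, biomarkers = biomarkers,
                 medication = medication,
                 medication_level = medication_level),
            class = "oa_case_spec")
}

#' Built-in library of representative IEM cases
#'
#' Case definitions for isovaleric aciduria (IVA), medium-chain acyl-CoA
#' dehydrogenase deficiency (MCADD), propionic aciduria (PA), glutaric
#' aciduria type 1 (GA1), methylmalonic aciduria (MMA) and
#' 5-oxoprolinuria, with default fold-changes placing the designated
#' biomarkers at z of roughly 5-15 under the default cohort model.
#'
#' @return Named list of `oa_case_spec` objects.
#' @export
iem_case_library <- function() {
  list(
    IVA = case_spec("IVA", c(
      "Isovalerylglycine" = 40, "3-Hydroxyisovaleric acid" = 15)),
    MCADD = case_spec("MCADD", c(
      "Hexanoylglycine" = 30, "Suberylglycine" = 30,
      "Phenylpropionylglycine" = 30)),
    PA = case_spec("PA", c(
      "Propionylglycine" = 30, "3-Hydroxypropionic acid" = 15,
      "2-Methylcitric acid" = 20, "Tiglylglycine" = 10)),
    GA1 = case_spec("GA1", c(
      "3-Hydroxyglutaric acid" = 40, "Glutaric acid" = 25)),
    MMA = case_spec("MMA", c(
      "Methylmalonic acid" = 60, "2-Methylcitric acid" = 15)),
    `5-oxoprolinuria` = case_spec("5-oxoprolinuria",
                                  c("Pyroglutamic acid" = 40))
  )
}

#' Simulate one patient case
#'
#' @param case An `oa_case_spec`.
#' @param spec An `oa_cohort_spec` describing the background population.
#' @param age_group Age group of the simulated patient.
#' @param seed Integer seed.
#' @param sample_id Identifier (defaults to the disease label).
#' @return One-sample tibble in the layout of [simulate_cohort()], with
#'   attributes `"case"` and `"spec"`.
#' @export
simulate_case <- function(case, spec, age_group = "0-2y", seed = 1,
                          sample_id = NULL) {
  stopifnot(inherits(case, "oa_case_spec"), inherits(spec, "oa_cohort_spec"))
  params <- dplyr::filter(spec$analytes, .data$age_group == !!age_group)
  unknown <- setdiff(c(names(case$biomarkers), case$medication),
                     params$analyte)
  if (length(unknown) > 0) {
    abort(sprintf("unknown biomarker(s): %s", paste(unknown, collapse = ", ")),
          class = "oa_synth_error")
  }
  sample_id <- sample_id %||% paste0("case_", gsub("[^0-9a-zA-Z]", "",
                                                   case$disease))
  one <- structure(spec, class = "oa_cohort_spec")
  one$n_per_group <- setNames(1L, age_group)
  # same seed as a plain control draw: fold-change 1 reproduces the control
  draw <- simulate_cohort(one, seed = seed, prefix = sample_id)
  draw <- draw |>
    dplyr::left_join(dplyr::select(params, "analyte", "present",
                                   "mean_log2", "lod_norm"),
                     by = "analyte") |>
    dplyr::mutate(
      fc = unname(case$biomarkers[.data$analyte]),
      base = dplyr::if_else(.data$present, .data$conc_norm, .data$lod_norm),
      conc_norm = dplyr::if_else(!is.na(.data$fc), .data$base * .data$fc,
                                 .data$conc_norm),
      conc_norm = dplyr::if_else(.data$analyte %in% case$medication,
                                 .data$lod_norm * case$medication_level,
                                 .data$conc_norm),
      below_lod = .data$conc_norm < .data$lod_norm,
      sample_id = !!sample_id
    ) |>
    dplyr::select("sample_id", "age_group", "creatinine", "analyte",
                  "conc_norm", "below_lod")
  attr(draw, "case") <- case
  attr(draw, "spec") <- spec
  draw
}

#' Simulated response ratios for a calibration batch
#'
#' For every externally calibrated analyte, generates `n_levels` nominal
#' concentrations equally log-spaced over the analyte's calibration range
#' and response ratios `slope * conc * (1 + e)` with multiplicative
#' Gaussian noise `e ~ N(0, cv)`. The true slope is scaled so ratios are
#' of order one at mid-range.
#'
#' @param panel An `oa_panel`.
#' @param cv Multiplicative noise level (0.05 = 5%).
#' @param n_levels Number of calibration levels.
#' @param seed Integer seed.
#' @return Tibble with `analyte`, `level`, `conc`, `ratio`, `true_slope`.
#' @export
simulate_calibration_ratios <- function(panel, cv = 0.05, n_levels = 6,
                                        seed = 1) {
  stopifnot(inherits(panel, "oa_panel"))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  cal <- dplyr::filter(panel$entries,
                       .data$quant_mode == "external_calibration")
  purrr::pmap_dfr(
    list(cal$name, cal$calib_low, cal$calib_high),
    function(name, lo, hi) {
      conc <- 2^seq(log2(lo), log2(hi), length.out = n_levels)
      slope <- 1 / sqrt(lo * hi)
      tibble::tibble(
        analyte = name, level = seq_len(n_levels), conc = conc,
        ratio = slope * conc * (1 + rnorm(n_levels, 0, cv)),
        true_slope = slope)
    })
}

#' Instrument model for rendering synthetic peak lists
#'
#' Per-analyte response factors (peak area counts x min per umol/L in the
#' injected solution) are drawn log-normally around a base value; peaks
#' are Gaussian in time with a common width; centroid masses carry a ppm
#' error draw; optional additive baseline noise.
#'
#' @param panel An `oa_panel`.
#' @param seed Integer seed for the response-factor draws.
#' @param base_rf Geometric-mean response factor.
#' @param rf_sdlog Log-normal spread of response factors.
#' @param peak_sigma Chromatographic peak SD, minutes. The default
#'   (0.007 min, about 1 s FWHM) reflects UHPLC peaks sharp enough to
#'   resolve the isomer pairs 0.05 min apart.
#' @param noise_sd Additive baseline noise SD, counts (0 = noise-free).
#' @param mass_error_ppm_sd SD of the centroid mass error, ppm.
#' @param scan_rate_hz Scan rate, Hz.
#' @param rt_span Chromatogram time span, minutes.
#' @return Object of class `oa_instrument_model`.
#' @export
instrument_model <- function(panel, seed = 1, base_rf = 2000,
                             rf_sdlog = 0.3, peak_sigma = 0.007,
                             noise_sd = 0, mass_error_ppm_sd = 0,
                             scan_rate_hz = 5, rt_span = c(0.3, 10)) {
  stopifnot(inherits(panel, "oa_panel"), peak_sigma > 0, base_rf > 0)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  analyte_rf <- tibble::tibble(
    name = panel$entries$name,
    rf = base_rf * exp(rnorm(nrow(panel$entries), 0, rf_sdlog)))
  istd_rf <- tibble::tibble(
    name = panel$istds$name,
    rf = base_rf * exp(rnorm(nrow(panel$istds), 0, rf_sdlog)))
  # analytes quantified by the relative-ISTD rule share their internal
  # standard's response factor: the generator embodies the method's
  # equal-response-factor premise
  rel <- panel$entries$quant_mode == "relative_istd"
  istd_of <- match(panel$entries$istd_name[rel], istd_rf$name)
  analyte_rf$rf[rel] <- istd_rf$rf[istd_of]
  structure(list(analyte_rf = analyte_rf, istd_rf = istd_rf,
                 peak_sigma = peak_sigma, noise_sd = noise_sd,
                 mass_error_ppm_sd = mass_error_ppm_sd,
                 scan_rate_hz = scan_rate_hz, rt_span = rt_span),
            class = "oa_instrument_model")
}

.render_one_sample <- function(truth, panel, model) {
  step <- 1 / (model$scan_rate_hz * 60)
  scans <- seq(model$rt_span[1], model$rt_span[2], by = step)
  sigma <- model$peak_sigma
  targets <- dplyr::bind_rows(
    panel$entries |>
      dplyr::select(name = "name", target_mz = "target_mz", rt = "rt") |>
      dplyr::inner_join(truth, by = c(name = "analyte")) |>
      dplyr::left_join(model$analyte_rf, by = "name"),
    panel$istds |>
      dplyr::select(name = "name", target_mz = "target_mz", rt = "rt",
                    conc_injected = "conc") |>
      dplyr::left_join(model$istd_rf, by = "name")
  )
  pk <- purrr::pmap_dfr(
    targets[c("name", "target_mz", "rt", "conc_injected", "rf")],
    function(name, target_mz, rt, conc_injected, rf) {
      area <- rf * conc_injected
      base <- if (model$noise_sd > 0) {
        abs(rnorm(length(scans), 0, model$noise_sd))
      } else {
        numeric(length(scans))
      }
      height <- area / (sigma * sqrt(2 * pi))
      signal <- if (conc_injected > 0) {
        height * exp(-0.5 * ((scans - rt) / sigma)^2)
      } else {
        0
      }
      y <- base + signal
      keep <- y > 0 & (base > 0 | abs(scans - rt) <= 5 * sigma)
      if (!any(keep)) return(NULL)
      mz <- target_mz *
        (1 + rnorm(sum(keep), 0, model$mass_error_ppm_sd) * 1e-6)
      tibble::tibble(rt = scans[keep], mz = mz, intensity = y[keep])
    })
  dplyr::arrange(pk, .data$rt, .data$mz)
}

#' Render instrument-level peak lists from ground-truth concentrations
#'
#' Converts per-sample analyte concentrations into centroided peak lists:
#' one Gaussian chromatographic peak per detected analyte at its panel
#' retention time, with area equal to response factor x injected
#' concentration, plus internal-standard peaks in every injection,
#' optional centroid mass error and additive baseline noise. Blank
#' injections contain only the internal standards.
#'
#' @param truths Tibble with columns `sample_id`, `sample_type`
#'   (`"calibrant"`, `"qc"`, `"blank"`, `"patient"`), `dilution_factor`,
#'   `creatinine` (mmol/L, `NA` for non-patient injections), `analyte`
#'   and `conc_injected` (umol/L in the injected solution). Blanks may
#'   omit analyte rows.
#' @param panel An `oa_panel`.
#' @param model An `oa_instrument_model`.
#' @param seed Integer seed for noise and mass-error draws.
#' @param out_dir Optional directory; when given, one peak-list TSV per
#'   sample plus `manifest.csv` are written there.
#' @return List with `peaklists` (named list of peak-list tibbles) and
#'   `manifest` (injection order, types, creatinine, dilution).
#' @export
render_instrument_data <- function(truths, panel, model, seed = 1,
                                   out_dir = NULL) {
  stopifnot(inherits(model, "oa_instrument_model"))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  meta <- truths |>
    dplyr::distinct(.data$sample_id, .data$sample_type,
                    .data$dilution_factor, .data$creatinine)
  stopifnot(!any(duplicated(meta$sample_id)))
  peaklists <- lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$sample_id[i]
    truth <- truths |>
      dplyr::filter(.data$sample_id == sid, !is.na(.data$analyte),
                    .data$conc_injected > 0) |>
      dplyr::select("analyte", "conc_injected")
    pk <- .render_one_sample(truth, panel, model)
    dplyr::mutate(pk, sample_id = sid, .before = 1)
  })
  names(peaklists) <- meta$sample_id
  manifest <- dplyr::mutate(meta, position = dplyr::row_number(),
                            .before = 1)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(peaklists)) {
      write_peaklist(peaklists[[sid]],
                     file.path(out_dir, paste0(sid, ".tsv")))
    }
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(peaklists = peaklists, manifest = manifest)
}

#' Ground-truth table for a calibration series
#'
#' `n_levels` calibrant injections spanning each analyte's calibration
#' range (equally log-spaced), in the layout expected by
#' [render_instrument_data()].
#'
#' @param panel An `oa_panel`.
#' @param n_levels Number of levels.
#' @return Truth tibble for the calibrant injections.
#' @export
calibrant_truths <- function(panel, n_levels = 6) {
  cal <- dplyr::filter(panel$entries,
                       .data$quant_mode == "external_calibration")
  tidyr::crossing(level = seq_len(n_levels),
                  analyte = cal$name) |>
    dplyr::left_join(
      dplyr::select(cal, analyte = "name", "calib_low", "calib_high"),
      by = "analyte") |>
    dplyr::mutate(
      sample_id = sprintf("cal_%d", .data$level),
      sample_type = "calibrant",
      dilution_factor = 1,
      creatinine = NA_real_,
      conc_injected = 2^(log2(.data$calib_low) +
                           (.data$level - 1) / (n_levels - 1) *
                           (log2(.data$calib_high) - log2(.data$calib_low)))
    ) |>
    dplyr::select("sample_id", "sample_type", "dilution_factor",
                  "creatinine", "analyte", "conc_injected", "level")
}

#' Ground-truth table for quantified samples
#'
#' Converts creatinine-normalized truths (as produced by
#' [simulate_cohort()] / [simulate_case()]) into injected concentrations:
#' `conc_injected = conc_norm * creatinine / dilution_factor`.
#'
#' @param quants Tibble with `sample_id`, `creatinine`, `analyte`,
#'   `conc_norm`.
#' @param dilution_factor Urine dilution factor applied before injection.
#' @return Truth tibble for [render_instrument_data()].
#' @export
patient_truths <- function(quants, dilution_factor = 16) {
  quants |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      sample_type = "patient",
      dilution_factor = dilution_factor,
      creatinine = .data$creatinine,
      analyte = .data$analyte,
      conc_injected = .data$conc_norm * .data$creatinine / dilution_factor)
}
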