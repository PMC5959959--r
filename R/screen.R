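# Age-stratified reference statistics and diagnostic z-score profiles.

# With SD fixed at log2(5)/3 ~ 0.774, a measurement at five times the LOD of
# a never-detected analyte scores z = 3 exactly; this pins the log base to 2.
.oa_sd_not_detected <- 0.774

#' Build age-stratified reference statistics from a control cohort
#'
#' For each analyte and age group (`"0-2y"`, `">2y"`), missing values and
#' values below the limit of detection are imputed at the LOD, the values
#' are log2-transformed, and their mean and standard deviation are stored.
#' When an analyte is never detected in the controls of an age group, its
#' reference is degenerate: the mean is set to `log2(LOD)` and the SD to
#' the fixed value 0.774 (= `log2(5)/3`), so that a measurement at five
#' times the LOD scores z = 3.
#'
#' @param controls Tibble of control-sample quantifications with columns
#'   `sample_id`, `age_group`, `analyte`, `conc_norm` (umol/mmol
#'   creatinine) and optionally `below_lod`.
#' @param lods Tibble with `analyte` and `lod_norm` (umol/mmol), or a
#'   single number used for every analyte.
#' @param sd_floor Degenerate detected cohorts (SD below this) are raised
#'   to this floor to avoid unbounded z-scores.
#' @param sd_not_detected SD assigned to never-detected analytes.
#' @return Tibble of class `oa_reference` with one row per analyte x age
#'   group: `mean_log2`, `sd_log2`, `n`, `n_imputed`, `lod_norm`,
#'   `not_detected`.
#' @export
build_reference <- function(controls, lods,
                            sd_floor = 0.1,
                            sd_not_detected = .oa_sd_not_detected) {
  stopifnot(all(c("age_group", "analyte", "conc_norm") %in% names(controls)))
  if (nrow(controls) == 0) {
    abort("control cohort is empty", class = "oa_reference_error")
  }
  if (is.numeric(lods) && is.null(dim(lods))) {
    lods <- tibble::tibble(analyte = unique(controls$analyte),
                           lod_norm = lods)
  }
  stopifnot(all(c("analyte", "lod_norm") %in% names(lods)))
  if (!"below_lod" %in% names(controls)) controls$below_lod <- FALSE
  n_groups <- controls |>
    dplyr::distinct(.data$age_group, .data$sample_id) |>
    dplyr::count(.data$age_group)
  if (any(n_groups$n < 2)) {
    abort("need >= 2 control samples per age group",
          class = "oa_reference_error")
  }
  ref <- controls |>
    dplyr::left_join(lods, by = "analyte") |>
    dplyr::mutate(
      imputed = is.na(.data$conc_norm) | .data$below_lod |
        .data$conc_norm < .data$lod_norm,
      value = pmax(dplyr::coalesce(.data$conc_norm, 0), .data$lod_norm)
    ) |>
    dplyr::group_by(.data$analyte, .data$age_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_imputed = sum(.data$imputed),
      mean_log2 = mean(log2(.data$value)),
      sd_log2 = sd(log2(.data$value)),
      lod_norm = .data$lod_norm[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      not_detected = .data$n_imputed == .data$n,
      mean_log2 = ifelse(.data$not_detected, log2(.data$lod_norm),
                         .data$mean_log2),
      sd_log2 = dplyr::case_when(
        not_detected ~ sd_not_detected,
        is.na(sd_log2) | sd_log2 < sd_floor ~ sd_floor,
        TRUE ~ sd_log2
      )
    )
  class(ref) <- c("oa_reference", class(ref))
  ref
}

#' Z-score of a creatinine-normalized concentration
#'
#' Standardized log2-scale deviation from the age-matched control
#' distribution: `z = (log2(max(conc_norm, lod_norm)) - mean_log2) /
#' sd_log2`. Values at or below the LOD are imputed at the LOD first, so a
#' never-detected analyte measured at or below its LOD scores exactly 0,
#' and at five times its LOD scores 3.
#'
#' @param conc_norm Normalized concentration, umol/mmol creatinine.
#' @param mean_log2,sd_log2,lod_norm Reference-statistics fields (vectors
#'   recycle as usual).
#' @return Numeric z-score vector.
#' @examples
#' zscore(5, mean_log2 = log2(1), sd_log2 = 0.774, lod_norm = 1) # ~ 3
#' @export
zscore <- function(conc_norm, mean_log2, sd_log2, lod_norm) {
  value <- pmax(dplyr::coalesce(conc_norm, 0), lod_norm)
  (log2(value) - mean_log2) / sd_log2
}

#' Z-score profile of one sample
#'
#' Scores every panel analyte of a quantified sample against the
#' age-matched reference and attaches interpretation flags: `elevated`
#' when z exceeds the significance threshold (default 3.0), `borderline`
#' in the band between the borderline threshold (default 2.5) and the
#' significance threshold, `decreased` below the negated borderline
#' threshold, `normal` otherwise. Analytes missing from the sample are
#' treated as not measured and imputed at the LOD.
#'
#' @param sample Tibble with `analyte`, `conc_norm` and optionally
#'   `ambiguous`; one sample.
#' @param ref An `oa_reference`.
#' @param age_group Age group of the sample (`"0-2y"` or `">2y"`); taken
#'   from an `age_group` column if present.
#' @param sample_id Identifier carried into the profile.
#' @param borderline,significant Flag thresholds on |z|.
#' @return Tibble of class `oa_profile`: one row per reference analyte
#'   with `conc_norm`, `z`, `flag`.
#' @export
profile_sample <- function(sample, ref, age_group = NULL,
                           sample_id = NULL,
                           borderline = 2.5, significant = 3.0) {
  stopifnot(inherits(ref, "oa_reference"), borderline < significant)
  if (is.null(age_group)) {
    if (!"age_group" %in% names(sample)) {
      abort("age_group must be given or present in `sample`",
            class = "oa_profile_error")
    }
    age_group <- unique(sample$age_group)
    stopifnot(length(age_group) == 1)
  }
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(sample)) {
      unique(sample$sample_id)[1]
    } else {
      NA_character_
    }
  }
  ref_g <- dplyr::filter(ref, .data$age_group == !!age_group)
  if (nrow(ref_g) == 0) {
    abort(sprintf("age group '%s' not present in reference", age_group),
          class = "oa_profile_error")
  }
  keep <- intersect(c("analyte", "conc_norm", "ambiguous"), names(sample))
  prof <- ref_g |>
    dplyr::select("analyte", "mean_log2", "sd_log2", "lod_norm",
                  "not_detected") |>
    dplyr::left_join(sample[keep], by = "analyte") |>
    dplyr::mutate(
      z = zscore(.data$conc_norm, .data$mean_log2, .data$sd_log2,
                 .data$lod_norm),
      flag = dplyr::case_when(
        z > significant ~ "elevated",
        z > borderline ~ "borderline",
        z < -borderline ~ "decreased",
        TRUE ~ "normal"
      ),
      sample_id = sample_id,
      age_group = age_group
    ) |>
    dplyr::relocate("sample_id", "age_group")
  attr(prof, "thresholds") <- c(borderline = borderline,
                                significant = significant)
  class(prof) <- c("oa_profile", class(prof))
  prof
}

#' Disease-to-biomarker interpretive map
#'
#' Editable lookup of characteristic urinary biomarkers for a set of
#' organic acidurias, used to annotate profile summaries and to define
#' synthetic cases. This is an interpretive aid, not a classifier.
#'
#' @return Tibble with `disease` and `analyte`.
#' @export
iem_biomarker_map <- function() {
  tibble::tribble(
    ~disease, ~analyte,
    "IVA", "Isovalerylglycine",
    "IVA", "3-Hydroxyisovaleric acid",
    "MCADD", "Hexanoylglycine",
    "MCADD", "Suberylglycine",
    "MCADD", "Phenylpropionylglycine",
    "PA", "Propionylglycine",
    "PA", "3-Hydroxypropionic acid",
    "PA", "2-Methylcitric acid",
    "PA", "Tiglylglycine",
    "GA1", "3-Hydroxyglutaric acid",
    "GA1", "Glutaric acid",
    "MMA", "Methylmalonic acid",
    "MMA", "2-Methylcitric acid",
    "MSUD", "2-Hydroxy-3-methylpentanoic acid",
    "MSUD", "2-Hydroxy-3-methylbutyric acid",
    "MADD", "Ethylmalonic acid",
    "MADD", "Glutaric acid",
    "MADD", "Suberic acid",
    "5-oxoprolinuria", "Pyroglutamic acid"
  )
}
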