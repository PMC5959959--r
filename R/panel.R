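# Targeted biomarker panel: mass arithmetic, panel I/O and validation,
# feature-to-analyte matching.

# Monoisotopic atomic masses (IUPAC/CODATA), Da. Panel chemistry spans CHNOS.
.oa_atomic_masses <- c(
  C = 12.0000000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.9720706900
)

# Mass removed on deprotonation: one H nucleus, electron retained.
.oa_proton_mass <- 1.00727646688

.parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) {
    return(setNames(integer(0), character(0)))
  }
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (paste(tokens, collapse = "") != formula) {
    abort(sprintf("cannot parse molecular formula '%s'", formula),
          class = "oa_formula_error")
  }
  elements <- gsub("[0-9]", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]", tokens),
                              gsub("[A-Za-z]", "", tokens), "1"))
  unknown <- setdiff(elements, names(.oa_atomic_masses))
  if (length(unknown) > 0) {
    abort(sprintf("unknown element symbol(s) in '%s': %s",
                  formula, paste(unknown, collapse = ", ")),
          class = "oa_formula_error")
  }
  counts <- tapply(counts, elements, sum)
  setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums tabulated monoisotopic atomic masses over the elements of a
#' molecular formula. Supported elements are C, H, N, O and S, which covers
#' the urinary organic-acid panel chemistry.
#'
#' @param formula Character vector of molecular formulas, e.g. `"C3H6O3"`.
#'   The empty string returns 0 (empty sum).
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("C3H6O3") # lactic acid, 90.0317
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    counts <- .parse_formula(f)
    if (length(counts) == 0) return(0)
    sum(.oa_atomic_masses[names(counts)] * counts)
  }, numeric(1), USE.NAMES = FALSE)
}

#' m/z of the deprotonated molecular ion
#'
#' Computes the `[M-H]-` ion mass observed in negative-mode electrospray:
#' the neutral monoisotopic mass minus the mass of a proton (a hydrogen
#' nucleus; the electron stays with the ion).
#'
#' @inheritParams monoisotopic_mass
#' @param digits Decimals for display rounding; `NULL` disables rounding.
#' @return Numeric vector of `[M-H]-` m/z values in Da.
#' @examples
#' mz_deprotonated("C3H6O3") # lactic acid, 89.0244
#' mz_deprotonated("C6H8O7") # citric acid, 191.0197
#' @export
mz_deprotonated <- function(formula, digits = 4) {
  counts <- lapply(formula, .parse_formula)
  n_h <- vapply(counts, function(x) {
    if ("H" %in% names(x)) x[["H"]] else 0L
  }, integer(1))
  if (any(n_h < 1)) {
    abort("formula must contain at least one H to deprotonate",
          class = "oa_formula_error")
  }
  mz <- monoisotopic_mass(formula) - .oa_proton_mass
  if (!is.null(digits)) mz <- round(mz, digits)
  mz
}

#' Path to the packaged panel definition files
#'
#' `oa_panel_file()` locates the packaged 75-analyte panel table (71 disease
#' and 4 medication markers, transcribed with assigned molecular formulas).
#' `oa_istd_file()` locates the companion internal-standard table; its m/z
#' values are computed from the parent-analyte formulas plus isotope-label
#' mass shifts and its spiked concentrations are synthetic defaults.
#'
#' @return Path to a CSV file.
#' @export
oa_panel_file <- function() {
  system.file("extdata", "table1_panel.csv", package = "oascreen",
              mustWork = TRUE)
}

#' @rdname oa_panel_file
#' @export
oa_istd_file <- function() {
  system.file("extdata", "istds_synthetic.csv", package = "oascreen",
              mustWork = TRUE)
}

.panel_cols <- readr::cols(
  name = readr::col_character(),
  hmdb_id = readr::col_character(),
  formula = readr::col_character(),
  target_mz = readr::col_double(),
  rt = readr::col_double(),
  istd_name = readr::col_character(),
  calib_low = readr::col_double(),
  calib_high = readr::col_double(),
  category = readr::col_character(),
  quant_mode = readr::col_character(),
  is_fragment = readr::col_logical()
)

#' Load and validate a targeted panel definition
#'
#' Reads the analyte table (and the internal-standard table) and enforces
#' the panel invariants: unique analyte names, positive target masses,
#' non-negative retention times, ordered calibration ranges, the rule that
#' `quant_mode == "relative_istd"` exactly when no calibration range is
#' given, and that every `istd_name` resolves to a known internal standard.
#' Violations raise a validation error naming the offending rows.
#'
#' @param path Path to the analyte CSV (defaults to the packaged panel).
#' @param istd_path Path to the internal-standard CSV.
#' @return An object of class `oa_panel`: a list with tibbles `entries`
#'   (one row per analyte, in panel order) and `istds` (name, target_mz,
#'   rt, spiked conc in umol/L).
#' @examples
#' panel <- load_panel()
#' dplyr::count(panel$entries, category)
#' @export
load_panel <- function(path = oa_panel_file(), istd_path = oa_istd_file()) {
  entries <- readr::read_csv(path, col_types = .panel_cols,
                             na = c("", "NA"), progress = FALSE)
  entries$formula[is.na(entries$formula)] <- ""
  istds <- readr::read_csv(istd_path, col_types = readr::cols(
    name = readr::col_character(),
    target_mz = readr::col_double(),
    rt = readr::col_double(),
    conc = readr::col_double()
  ), progress = FALSE)
  panel <- structure(list(entries = entries, istds = istds),
                     class = "oa_panel")
  validate_panel(panel)
  panel
}

#' Write a panel definition back to CSV
#'
#' Inverse of [load_panel()]; `load_panel(write_panel(p))` round-trips.
#'
#' @param panel An `oa_panel`.
#' @param path,istd_path Output CSV paths.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, istd_path = NULL) {
  stopifnot(inherits(panel, "oa_panel"))
  out <- panel$entries
  readr::write_csv(out, path, na = "")
  if (!is.null(istd_path)) readr::write_csv(panel$istds, istd_path)
  invisible(path)
}

#' Validate panel invariants
#'
#' @param panel An `oa_panel`.
#' @return `panel`, invisibly; raises a classed error listing offending
#'   rows otherwise.
#' @export
validate_panel <- function(panel) {
  e <- panel$entries
  problems <- character(0)
  bad_row <- function(i, msg) sprintf("row %d (%s): %s", i, e$name[i], msg)
  dup <- duplicated(e$name)
  if (any(dup)) {
    problems <- c(problems, vapply(which(dup), bad_row,
                                   msg = "duplicate analyte name", ""))
  }
  for (i in seq_len(nrow(e))) {
    if (!is.finite(e$target_mz[i]) || e$target_mz[i] <= 0) {
      problems <- c(problems, bad_row(i, "target_mz must be > 0"))
    }
    if (!is.finite(e$rt[i]) || e$rt[i] < 0) {
      problems <- c(problems, bad_row(i, "rt must be >= 0"))
    }
    has_range <- !is.na(e$calib_low[i]) && !is.na(e$calib_high[i])
    if (has_range && e$calib_low[i] >= e$calib_high[i]) {
      problems <- c(problems, bad_row(i, "calib_low must be < calib_high"))
    }
    if (has_range != (e$quant_mode[i] == "external_calibration")) {
      problems <- c(problems, bad_row(
        i, "quant_mode must be relative_istd exactly when no calibration range"))
    }
    if (!e$istd_name[i] %in% panel$istds$name) {
      problems <- c(problems, bad_row(
        i, sprintf("istd_name '%s' not in ISTD table", e$istd_name[i])))
    }
  }
  if (length(problems) > 0) {
    abort(c("panel validation failed", problems), class = "oa_panel_error")
  }
  invisible(panel)
}

#' @export
print.oa_panel <- function(x, ...) {
  n_cal <- sum(x$entries$quant_mode == "external_calibration")
  cat(sprintf(
    "<oa_panel> %d analytes (%d disease, %d medication), %d calibrated, %d ISTDs\n",
    nrow(x$entries), sum(x$entries$category == "disease"),
    sum(x$entries$category == "medication"), n_cal, nrow(x$istds)))
  invisible(x)
}

#' Match an observed feature to panel analytes
#'
#' Finds all panel entries whose target mass lies within a ppm tolerance of
#' the observed m/z and whose retention time lies within an absolute window,
#' ranked by retention-time deviation then mass deviation. When several
#' analytes match (e.g. the adipic acid / 3-methylglutaric acid isomer pair,
#' identical mass and retention times 0.07 min apart), all rows carry
#' `ambiguous = TRUE`; such peaks need the full biomarker profile and the
#' clinical picture to resolve.
#'
#' @param panel An `oa_panel`.
#' @param mz Observed m/z (Da).
#' @param rt Observed retention time (minutes).
#' @param mz_tol_ppm Mass tolerance in ppm (default 10, typical QTOF
#'   accuracy).
#' @param rt_tol_min Retention-time tolerance in minutes (default 0.2).
#' @return Tibble of matching entries with `delta_mz` (Da), `delta_rt`
#'   (min) and `ambiguous`; zero rows when nothing matches.
#' @examples
#' panel <- load_panel()
#' match_feature(panel, 117.0193, 2.89) # methylmalonic, not succinic
#' @export
match_feature <- function(panel, mz, rt, mz_tol_ppm = 10, rt_tol_min = 0.2) {
  stopifnot(inherits(panel, "oa_panel"), mz_tol_ppm > 0, rt_tol_min > 0)
  obs_mz <- mz
  obs_rt <- rt
  hits <- panel$entries |>
    dplyr::mutate(
      delta_mz = abs(.data$target_mz - obs_mz),
      delta_rt = abs(.data$rt - obs_rt)
    ) |>
    dplyr::filter(
      .data$delta_mz / .data$target_mz * 1e6 <= mz_tol_ppm,
      .data$delta_rt <= rt_tol_min
    ) |>
    dplyr::arrange(.data$delta_rt, .data$delta_mz)
  hits$ambiguous <- rep(nrow(hits) > 1, nrow(hits))
  hits
}
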