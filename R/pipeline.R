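# End-to-end pipeline commands with config, logging and versioned outputs.

#' Pipeline run configuration
#'
#' Collects the knobs shared by the pipeline commands. All referenced
#' files must exist and the borderline threshold must lie below the
#' significance threshold.
#'
#' @param panel_path Panel CSV (defaults to the packaged panel).
#' @param istd_path Internal-standard CSV.
#' @param mz_tol_ppm,rt_window Extraction/integration tolerances.
#' @param z_borderline,z_significant Profile flag thresholds.
#' @param weighting Calibration weighting (`"none"` or `"1/x"`).
#' @param out_dir Output directory for artifacts.
#' @param seed Integer seed for the stochastic commands.
#' @return Object of class `oa_config` (a named list with a stable hash).
#' @export
run_config <- function(panel_path = oa_panel_file(),
                       istd_path = oa_istd_file(),
                       mz_tol_ppm = 10, rt_window = 0.5,
                       z_borderline = 2.5, z_significant = 3.0,
                       weighting = "none",
                       out_dir = tempfile("oascreen_run_"),
                       seed = 1) {
  if (!file.exists(panel_path)) {
    abort(sprintf("panel file not found: %s", panel_path),
          class = "oa_config_error")
  }
  if (!file.exists(istd_path)) {
    abort(sprintf("ISTD file not found: %s", istd_path),
          class = "oa_config_error")
  }
  if (!(z_borderline < z_significant)) {
    abort("z_borderline must be below z_significant",
          class = "oa_config_error")
  }
  cfg <- list(panel_path = panel_path, istd_path = istd_path,
              mz_tol_ppm = mz_tol_ppm, rt_window = rt_window,
              z_borderline = z_borderline, z_significant = z_significant,
              weighting = weighting, out_dir = out_dir,
              seed = as.integer(seed))
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "oa_config")
}

.write_artifact <- function(df, path, cfg, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  header <- sprintf("# oascreen %s | config %s | seed %d",
                    as.character(utils::packageVersion("oascreen")),
                    cfg$hash, cfg$seed)
  writeLines(header, path)
  suppressWarnings(readr::write_csv(df, path, append = TRUE,
                                    col_names = TRUE))
  path
}

#' Run a pipeline command
#'
#' Commands:
#' \describe{
#'   \item{`simulate`}{Simulate a control cohort plus the built-in IEM
#'     case library at the configured seed; writes `cohort.csv`,
#'     `cases.csv` and `lods.csv`.}
#'   \item{`calibrate`}{Fit calibration curves from a response-ratio
#'     table (`inputs$ratios` with `analyte`, `conc`, `ratio`); writes
#'     `curves.csv`.}
#'   \item{`quantify`}{Quantify response ratios against curves from a
#'     prior `calibrate` (`inputs$ratios`, `inputs$curves`); errors when
#'     no calibration is supplied.}
#'   \item{`reference`}{Build reference statistics from control
#'     quantifications (`inputs$controls`, `inputs$lods`); writes
#'     `reference.csv`.}
#'   \item{`screen`}{Profile samples (`inputs$samples`) against a
#'     reference (`inputs$reference`); writes `profiles.csv` and one plot
#'     per sample.}
#'   \item{`compare`}{Method comparison on paired data
#'     (`inputs$paired`); writes `comparison.csv`.}
#' }
#' Every artifact embeds the package version, config hash and seed in a
#' leading comment line; numeric columns are written at 6 significant
#' digits so identical configs reproduce identical bytes.
#'
#' @param command One of `"simulate"`, `"calibrate"`, `"quantify"`,
#'   `"reference"`, `"screen"`, `"compare"`.
#' @param config An `oa_config`.
#' @param inputs Named list of input tibbles/paths, per command.
#' @return Invisibly, a list with `artifacts` (paths written) and the
#'   command's main result object.
#' @export
run_pipeline <- function(command = c("simulate", "calibrate", "quantify",
                                     "reference", "screen", "compare"),
                         config = run_config(), inputs = list()) {
  command <- match.arg(command)
  stopifnot(inherits(config, "oa_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- load_panel(config$panel_path, config$istd_path)
  artifacts <- character(0)
  result <- NULL
  emit <- function(df, file) {
    p <- .write_artifact(df, file.path(config$out_dir, file), config)
    artifacts <<- c(artifacts, p)
  }
  if (command == "simulate") {
    spec <- cohort_spec(panel)
    cohort <- simulate_cohort(spec, seed = config$seed)
    cases <- purrr::imap_dfr(iem_case_library(), function(cs, nm) {
      simulate_case(cs, spec, seed = config$seed + which(
        names(iem_case_library()) == nm))
    })
    emit(cohort, "cohort.csv")
    emit(cases, "cases.csv")
    emit(spec_lods(spec), "lods.csv")
    result <- list(cohort = cohort, cases = cases, spec = spec)
  } else if (command == "calibrate") {
    ratios <- .as_input_table(inputs$ratios, "ratios",
                              c("analyte", "conc", "ratio"))
    curves <- ratios |>
      dplyr::group_by(.data$analyte) |>
      dplyr::group_modify(function(d, key) {
        glance(fit_calibration(d, analyte = key$analyte[[1]],
                               weighting = config$weighting))[-1]
      }) |>
      dplyr::ungroup()
    emit(curves, "curves.csv")
    result <- curves
  } else if (command == "quantify") {
    if (is.null(inputs$curves)) {
      abort("quantify requires a calibration (inputs$curves)",
            class = "oa_input_error")
    }
    ratios <- .as_input_table(inputs$ratios, "ratios",
                              c("sample_id", "analyte", "ratio"))
    curves <- .as_input_table(inputs$curves, "curves",
                              c("analyte", "slope", "intercept"))
    quants <- ratios |>
      dplyr::left_join(curves, by = "analyte") |>
      dplyr::mutate(
        conc = pmax((.data$ratio - .data$intercept) / .data$slope, 0),
        below_lod = (.data$ratio - .data$intercept) / .data$slope <= 0)
    emit(quants, "quants.csv")
    result <- quants
  } else if (command == "reference") {
    controls <- .as_input_table(inputs$controls, "controls",
                                c("sample_id", "age_group", "analyte",
                                  "conc_norm"))
    lods <- .as_input_table(inputs$lods, "lods", c("analyte", "lod_norm"))
    ref <- build_reference(controls, lods)
    emit(tibble::as_tibble(ref), "reference.csv")
    result <- ref
  } else if (command == "screen") {
    samples <- .as_input_table(inputs$samples, "samples",
                               c("sample_id", "age_group", "analyte",
                                 "conc_norm"))
    ref <- inputs$reference
    if (!inherits(ref, "oa_reference")) {
      ref <- .as_input_table(ref, "reference",
                             c("analyte", "age_group", "mean_log2",
                               "sd_log2", "lod_norm"))
      class(ref) <- c("oa_reference", class(ref))
    }
    profs <- samples |>
      dplyr::group_split(.data$sample_id) |>
      purrr::map(function(d) {
        profile_sample(d, ref,
                       borderline = config$z_borderline,
                       significant = config$z_significant)
      })
    all_prof <- dplyr::bind_rows(lapply(profs, tibble::as_tibble))
    emit(all_prof, "profiles.csv")
    for (pr in profs) {
      f <- file.path(config$out_dir,
                     paste0("profile_", pr$sample_id[1], ".png"))
      render_profile_plot(pr, f)
      artifacts <- c(artifacts, f)
    }
    result <- profs
  } else if (command == "compare") {
    paired <- .as_input_table(inputs$paired, "paired",
                              c("analyte", "conc_test", "conc_ref"))
    report <- compare_methods(paired)
    emit(tibble::as_tibble(report), "comparison.csv")
    result <- report
  }
  invisible(list(artifacts = artifacts, result = result,
                 config_hash = config$hash))
}

.as_input_table <- function(x, what, need) {
  if (is.null(x)) {
    abort(sprintf("missing input '%s'", what), class = "oa_input_error")
  }
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) {
      abort(sprintf("input file for '%s' not found: %s", what, x),
            class = "oa_input_error")
    }
    x <- readr::read_csv(x, show_col_types = FALSE, comment = "#")
  }
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("input '%s' lacks column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "oa_input_error")
  }
  tibble::as_tibble(x)
}
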