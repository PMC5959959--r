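# Centroided peak-list I/O, extracted ion chromatograms, peak integration.

#' Read a centroided peak list
#'
#' The native interchange format is a plain TSV with columns `sample_id`,
#' `rt` (minutes), `mz` (Da) and `intensity` (counts), one row per centroid,
#' '.' as decimal separator. Inputs are assumed mass-calibrated.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `sample_id`, `rt`, `mz`, `intensity`.
#' @export
read_peaklist <- function(path) {
  pk <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    rt = readr::col_double(),
    mz = readr::col_double(),
    intensity = readr::col_double()
  ), progress = FALSE)
  validate_peaklist(pk)
  pk
}

#' @rdname read_peaklist
#' @param peaks Peak-list tibble to write.
#' @export
write_peaklist <- function(peaks, path) {
  readr::write_tsv(peaks, path)
  invisible(path)
}

validate_peaklist <- function(peaks) {
  need <- c("rt", "mz", "intensity")
  missing <- setdiff(need, names(peaks))
  if (length(missing) > 0) {
    abort(sprintf("peak list lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "oa_peaklist_error")
  }
  if (any(peaks$intensity < 0, na.rm = TRUE)) {
    abort("peak intensities must be >= 0", class = "oa_peaklist_error")
  }
  invisible(peaks)
}

#' Read centroided MS1 spectra from an mzML file
#'
#' Thin wrapper over Bioconductor \pkg{mzR} mapping centroid MS1 scans in
#' negative mode onto the native peak-list layout. Profile-mode files are
#' not supported.
#'
#' @param path Path to an mzML file.
#' @param sample_id Sample identifier to attach (defaults to file name).
#' @return Peak-list tibble as from [read_peaklist()].
#' @export
read_mzml <- function(path, sample_id = basename(path)) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("read_mzml() requires the mzR package", class = "oa_peaklist_error")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  ms1 <- which(hdr$msLevel == 1)
  pk <- purrr::map_dfr(ms1, function(i) {
    sp <- mzR::peaks(handle, i)
    tibble::tibble(rt = hdr$retentionTime[i] / 60,
                   mz = sp[, 1], intensity = sp[, 2])
  })
  pk <- dplyr::mutate(pk, sample_id = sample_id, .before = 1)
  validate_peaklist(pk)
  pk
}

#' Extract an ion chromatogram at a target mass
#'
#' Sums centroid intensities within a ppm window of the target m/z, scan by
#' scan. Every scan in the input yields one chromatogram point; scans with
#' no centroid inside the window contribute zero, so the trace keeps the
#' full time axis for noise estimation.
#'
#' @param peaks Peak-list tibble (one sample) with `rt`, `mz`, `intensity`.
#' @param target_mz Target m/z in Da.
#' @param mz_tol_ppm Half-width of the extraction window in ppm.
#' @return Tibble with `rt` (ascending) and `intensity`, one row per scan.
#' @export
extract_eic <- function(peaks, target_mz, mz_tol_ppm = 10) {
  stopifnot(mz_tol_ppm > 0, target_mz > 0)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(rt = numeric(0), intensity = numeric(0)))
  }
  if ("sample_id" %in% names(peaks) &&
      dplyr::n_distinct(peaks$sample_id) > 1) {
    abort("extract_eic() expects a single sample; split by sample_id first",
          class = "oa_peaklist_error")
  }
  tol_da <- target_mz * mz_tol_ppm / 1e6
  scans <- sort(unique(peaks$rt))
  inwin <- peaks[abs(peaks$mz - target_mz) <= tol_da, c("rt", "intensity")]
  summed <- tapply(inwin$intensity, factor(inwin$rt, levels = scans), sum)
  tibble::tibble(rt = scans,
                 intensity = as.numeric(ifelse(is.na(summed), 0, summed)))
}

#' Integrate a chromatographic peak
#'
#' Locates the apex within `expected_rt +/- rt_window`, walks outward to
#' the surrounding local minima (bounded by the window) and integrates
#' trapezoidally between them. Among candidate local maxima that clear a
#' rough noise floor, the one closest to the expected retention time is
#' taken as the apex, so a larger isobaric neighbour eluting inside the
#' search window (e.g. the adipic acid / 3-methylglutaric acid pair) does
#' not capture the integration; when no candidate clears the floor the
#' window maximum is used. The noise level is a robust scale estimate --
#' 1.4826 x the median absolute deviation of the chromatogram intensities
#' outside the peak region, floored at 1 count -- and the signal-to-noise
#' ratio is apex height over noise. A peak is called `found` only when its
#' height exceeds 3 x noise; otherwise the area is reported as 0.
#'
#' @param eic Tibble from [extract_eic()].
#' @param expected_rt Expected retention time (minutes).
#' @param rt_window Half-width of the search window (minutes).
#' @return One-row tibble: `area` (counts x min), `height`, `rt_apex`,
#'   `snr`, `noise`, `found`.
#' @export
integrate_peak <- function(eic, expected_rt, rt_window = 0.5) {
  stopifnot(rt_window > 0)
  empty <- tibble::tibble(area = 0, height = 0, rt_apex = NA_real_,
                          snr = 0, noise = NA_real_, found = FALSE)
  if (nrow(eic) == 0) return(empty)
  rt <- eic$rt
  y <- eic$intensity
  win <- which(abs(rt - expected_rt) <= rt_window)
  if (length(win) == 0 || all(y[win] <= 0)) {
    noise <- max(1, mad(y, constant = 1.4826))
    return(dplyr::mutate(empty, noise = noise))
  }
  # candidate apexes: local maxima in the window above a rough noise floor
  rough <- max(1, mad(y, constant = 1.4826))
  is_lmax <- vapply(win, function(i) {
    y[i] > 0 &&
      (i == 1 || y[i] >= y[i - 1]) &&
      (i == length(y) || y[i] >= y[i + 1])
  }, logical(1))
  cand <- win[is_lmax & y[win] > 3 * rough]
  apex <- if (length(cand) > 0) {
    cand[order(abs(rt[cand] - expected_rt), -y[cand])][1]
  } else {
    win[which.max(y[win])]
  }
  # walk to local minima (or window/trace edge) on each side of the apex
  left <- apex
  while (left > min(win) && y[left - 1] <= y[left]) left <- left - 1
  right <- apex
  while (right < max(win) && y[right + 1] <= y[right]) right <- right + 1
  region <- left:right
  idx_out <- setdiff(seq_along(y), region)
  noise <- if (length(idx_out) >= 3) {
    max(1, mad(y[idx_out], constant = 1.4826))
  } else {
    1
  }
  height <- y[apex]
  snr <- height / noise
  found <- height > 3 * noise
  area <- if (length(region) >= 2) {
    sum(diff(rt[region]) * (head(y[region], -1) + tail(y[region], -1)) / 2)
  } else {
    0
  }
  tibble::tibble(area = if (found) area else 0,
                 height = height, rt_apex = rt[apex],
                 snr = snr, noise = noise, found = found)
}

#' Measure all panel targets in one sample
#'
#' Runs [extract_eic()] and [integrate_peak()] for every panel analyte and
#' every internal standard in a single injection.
#'
#' @param peaks Peak-list tibble for one sample.
#' @param panel An `oa_panel`.
#' @param mz_tol_ppm Extraction tolerance, ppm.
#' @param rt_window Integration half-window, minutes.
#' @param rt_tol_min Retention-time tolerance used for the isobar-ambiguity
#'   check (see [match_feature()]).
#' @return Tibble with one row per target: `name`, `kind`
#'   (`"analyte"`/`"istd"`), the [integrate_peak()] columns, and the
#'   `ambiguous` flag from [match_feature()] applied at the target's own
#'   coordinates.
#' @export
measure_sample <- function(peaks, panel, mz_tol_ppm = 10, rt_window = 0.1,
                           rt_tol_min = 0.2) {
  stopifnot(inherits(panel, "oa_panel"))
  targets <- dplyr::bind_rows(
    dplyr::transmute(panel$entries, name = .data$name,
                     target_mz = .data$target_mz, rt = .data$rt,
                     kind = "analyte"),
    dplyr::transmute(panel$istds, name = .data$name,
                     target_mz = .data$target_mz, rt = .data$rt,
                     kind = "istd")
  )
  meas <- purrr::pmap_dfr(targets, function(name, target_mz, rt, kind) {
    eic <- extract_eic(peaks, target_mz, mz_tol_ppm)
    m <- integrate_peak(eic, rt, rt_window)
    dplyr::mutate(m, name = name, kind = kind, .before = 1)
  })
  amb <- vapply(seq_len(nrow(panel$entries)), function(i) {
    nrow(match_feature(panel, panel$entries$target_mz[i],
                       panel$entries$rt[i], mz_tol_ppm,
                       rt_tol_min)) > 1
  }, logical(1))
  meas |>
    dplyr::left_join(
      tibble::tibble(name = panel$entries$name, ambiguous = amb),
      by = "name") |>
    dplyr::mutate(ambiguous = dplyr::coalesce(.data$ambiguous, FALSE))
}
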