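# ggplot2 visualisations for profiles, calibrations and method comparison.

#' Plot a z-score profile
#'
#' One glyph per panel analyte in panel order, with horizontal guides at
#' the borderline (+/-2.5) and significance (+/-3.0) thresholds; flagged
#' analytes are highlighted and labelled. Deterministic given the profile.
#'
#' @param object An `oa_profile` from [profile_sample()].
#' @param label_flagged Label analytes whose flag is not `"normal"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oa_profile
#' @export
autoplot.oa_profile <- function(object, label_flagged = TRUE, ...) {
  thr <- attr(object, "thresholds") %||%
    c(borderline = 2.5, significant = 3)
  df <- dplyr::mutate(tibble::as_tibble(object),
                      analyte = factor(.data$analyte,
                                       levels = unique(.data$analyte)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$analyte, y = .data$z)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * thr[["borderline"]],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * thr[["significant"]],
                        linetype = "dotted", colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag), size = 1.8) +
    ggplot2::scale_colour_manual(values = c(
      normal = "grey40", borderline = "orange",
      elevated = "red3", decreased = "steelblue"), drop = FALSE) +
    ggplot2::labs(
      x = NULL, y = "z-score",
      title = paste0("Z-score profile",
                     if (!is.na(df$sample_id[1])) paste0(": ", df$sample_id[1]),
                     " (", df$age_group[1], ")")) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, hjust = 1, vjust = 0.5, size = 5))
  if (label_flagged && any(df$flag != "normal")) {
    p <- p + ggplot2::geom_text(
      data = dplyr::filter(df, .data$flag != "normal"),
      ggplot2::aes(label = .data$analyte),
      size = 2.2, vjust = -0.8)
  }
  p
}

#' Render a z-score profile plot to a file
#'
#' @param profile An `oa_profile`.
#' @param out_path Output image path (`.png` or `.svg`).
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return `out_path`, invisibly.
#' @export
render_profile_plot <- function(profile, out_path, width = 9, height = 4,
                                dpi = 150) {
  p <- autoplot.oa_profile(profile)
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = dpi)
  invisible(out_path)
}

#' Plot a calibration curve with its fit
#'
#' @param object An `oa_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oa_calibration
#' @export
autoplot.oa_calibration <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$conc, y = .data$ratio)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Nominal concentration (µmol/L)", y = "Response ratio",
      title = object$analyte,
      subtitle = sprintf("slope %.4g, R² = %.4f", object$slope,
                         object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot a Passing-Bablok method comparison
#'
#' Scatter of test versus reference concentrations with the identity line
#' and the fitted Passing-Bablok line.
#'
#' @param object An `oa_pb` from [passing_bablok()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oa_pb
#' @export
autoplot.oa_pb <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60",
                         linetype = "dashed") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red3") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Reference method (µmol/L)", y = "Test method (µmol/L)",
      subtitle = sprintf(
        "slope %.3f [%.3f, %.3f], intercept %.3f [%.3f, %.3f], n = %d",
        object$slope, object$slope_ci[1], object$slope_ci[2],
        object$intercept, object$intercept_ci[1], object$intercept_ci[2],
        object$n)) +
    ggplot2::theme_minimal()
}
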