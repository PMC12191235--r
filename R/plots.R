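#' Plot Kaplan-Meier curves
#'
#' Step plot of per-group survival over hours post-irradiation.
#'
#' @param object A [km_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$time, y = .data$survival, colour = .data$group
  )) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Hours post-irradiation", y = "Survival probability",
      colour = "Group"
    ) +
    ggplot2::theme_minimal()
}

#' Plot single-cell GEDI ratio trajectories
#'
#' Per-cell ratio traces over the imaging schedule with the death threshold
#' drawn as a dashed line.
#'
#' @param tracks Track observations with `track_id`, `t`, `mean_red`,
#'   `mean_green` and optionally `group`.
#' @param theta Death threshold to draw.
#' @param red_floor Passed to [gedi_ratio()].
#' @return A ggplot.
#' @export
plot_gedi_tracks <- function(tracks, theta = 1, red_floor = 0) {
  d <- tracks
  if (!"group" %in% names(d)) d$group <- "all"
  d$ratio <- gedi_ratio(d$mean_green, d$mean_red, red_floor)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$t, y = .data$ratio, group = .data$track_id
  )) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_point(size = 0.6, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = theta, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Hours post-irradiation", y = "GEDI ratio (green/red)") +
    ggplot2::theme_minimal()
}

#' Plot a foci timecourse summary
#'
#' Mean puncta per cell with SEM error bars, by group over time.
#'
#' @param summary A [foci_timecourse()] tibble.
#' @return A ggplot.
#' @export
plot_foci_timecourse <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$timepoint, y = .data$mean_count, colour = .data$group
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_count - .data$sem,
      ymax = .data$mean_count + .data$sem
    ), width = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "Hours post-irradiation", y = "Puncta per cell",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot a flow-cytometry fluorescence histogram with its positivity gate
#'
#' @param events Event tibble with `fluor`.
#' @param gate Optional gate value (vertical line), e.g. from
#'   [gate_positive()].
#' @return A ggplot.
#' @export
plot_flow_hist <- function(events, gate = NULL) {
  p <- ggplot2::ggplot(events, ggplot2::aes(x = .data$fluor)) +
    ggplot2::geom_histogram(bins = 100, fill = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Fluorescence (a.u., log scale)", y = "Events") +
    ggplot2::theme_minimal()
  if (!is.null(gate)) {
    p <- p + ggplot2::geom_vline(xintercept = gate, colour = "red",
                                 linetype = "dashed")
  }
  p
}

#' Plot a mitochondrial stress-test OCR trace
#'
#' @param trace OCR trace tibble (`time_min`, `ocr`, `phase`).
#' @return A ggplot.
#' @export
plot_ocr_trace <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(
    x = .data$time_min, y = .data$ocr, colour = .data$phase
  )) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Time (min)", y = "OCR (pmol/min)",
                  colour = "Phase") +
    ggplot2::theme_minimal()
}
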