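# ggplot2 views of the main result types.

#' Plot method for `bcg_signal` objects
#' @param object The object to plot.
#' @param ... Unused.
#' @method autoplot bcg_signal
#' @export
autoplot.bcg_signal <- function(object, beats = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$bcg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "BCG (arbitrary units)") +
    ggplot2::theme_minimal()
  if (!is.null(beats) && nrow(beats)) {
    p <- p + ggplot2::geom_vline(xintercept = beats$time_s,
                                 colour = "steelblue", alpha = 0.5)
  }
  p
}

#' Plot method for `peak_set` objects
#' @param object The object to plot.
#' @param ... Unused.
#' @method autoplot peak_set
#' @export
autoplot.peak_set <- function(object, ...) {
  if (!"label" %in% names(object)) object$label <- "unlabeled"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$height, y = .data$prominence,
                                       colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Peak height (BCG units)", y = "Prominence (BCG units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot method for `bcg_snr` objects
#' @param object The object to plot.
#' @param ... Unused.
#' @method autoplot bcg_snr
#' @export
autoplot.bcg_snr <- function(object, ...) {
  ggplot2::ggplot(object$psd, ggplot2::aes(x = .data$freq_bpm, y = .data$psd)) +
    ggplot2::annotate("rect", xmin = object$band_bpm[1L], xmax = object$band_bpm[2L],
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, object$max_bpm)) +
    ggplot2::labs(x = "Frequency (beats per minute)", y = "Power spectral density",
                  title = sprintf("SNR = %.2f%s", object$snr,
                                  if (!is.na(object$mode)) paste0(" (", object$mode, ")") else "")) +
    ggplot2::theme_minimal()
}

#' Plot method for `bcg_trend` objects
#' @param object The object to plot.
#' @param ... Unused.
#' @method autoplot bcg_trend
#' @export
autoplot.bcg_trend <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(x = "Normalized dive time", y = "Heart rate (beats per minute)") +
    ggplot2::theme_minimal()
}

#' Plot method for `bcg_equivalence` objects
#' @param object The object to plot.
#' @param ... Unused.
#' @method autoplot bcg_equivalence
#' @export
autoplot.bcg_equivalence <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$ecg, y = .data$bcg)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "ECG heart rate (beats per minute)",
                  y = "BCG heart rate (beats per minute)") +
    ggplot2::theme_minimal()
}

#' Depth profile with dives and motionless windows
#'
#' @param depth Depth tag series.
#' @param dives Optional [segment_dives()] table; retained dives shaded.
#' @param windows Optional [find_motionless()] table.
#' @return A ggplot.
#' @export
plot_depth_profile <- function(depth, dives = NULL, windows = NULL) {
  p <- ggplot2::ggplot(depth, ggplot2::aes(x = .data$time_s, y = .data$depth_m)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Time (s)", y = "Depth (m)") +
    ggplot2::theme_minimal()
  if (!is.null(windows) && nrow(windows)) {
    p <- p + ggplot2::annotate("rect", xmin = windows$start_s, xmax = windows$end_s,
                               ymin = -Inf, ymax = Inf, fill = "pink", alpha = 0.4)
  }
  if (!is.null(dives) && any(dives$retained)) {
    keep <- dives[dives$retained, ]
    p <- p + ggplot2::annotate("rect", xmin = keep$start_s, xmax = keep$end_s,
                               ymin = -Inf, ymax = Inf, alpha = 0.08)
  }
  p
}
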