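# ggplot2 visualization methods. Decibel conversion happens only here, at
# the visualization boundary; all quantification stays in linear power.

#' Plot a spectrogram
#'
#' @param object A `spectrogram`.
#' @param db Scale power to decibels (`10 * log10`) for display (default
#'   `TRUE` for raw power).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrogram <- function(object, db = object$norm_state == "raw", ...) {
  d <- tidy(object)
  if (db) d$power <- 10 * log10(pmax(d$power, .Machine$double.xmin))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$freq,
                                  fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (db) "power (dB)" else "power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a comodulogram
#'
#' @param object A `comodulogram`.
#' @param ... Unused.
#' @return A ggplot (masked cells are blank).
#' @export
autoplot.comodulogram <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phase_freq, y = .data$amp_freq,
                                  fill = .data$mi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MI", na.value = "grey90") +
    ggplot2::labs(x = "phase frequency (Hz)", y = "amplitude frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a connectivity track
#'
#' @param object A `connectivity_track` (wPLI or PSI).
#' @param ... Unused.
#' @return A ggplot; PSI uses a diverging scale centered at zero (positive
#'   = first region leads).
#' @export
autoplot.connectivity_track <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$freq,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
  if (object$metric == "psi") {
    lim <- max(abs(d$value), na.rm = TRUE)
    p + ggplot2::scale_fill_gradient2(name = "PSI", limits = c(-lim, lim))
  } else {
    p + ggplot2::scale_fill_viridis_c(name = "wPLI", limits = c(0, 1))
  }
}

#' Band z-power time courses from an experiment report
#'
#' @param report An `experiment_report`.
#' @param metric Metric name (default `"delta_z"`).
#' @return A ggplot of per-condition epoch means.
#' @export
plot_metric_by_condition <- function(report, metric = "delta_z") {
  stopifnot(inherits(report, "experiment_report"))
  d <- report$metrics[report$metrics$metric == metric, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$value,
                                  colour = .data$epoch)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
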