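#' Raster plot of an analyzed recording
#'
#' Spike raster over electrodes with detected network bursts shaded, the
#' standard way MEA recordings are displayed.
#'
#' @param object An `mea_analysis` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mea_analysis <- function(object, ...) {
  spikes <- tibble::as_tibble(object$spikes)
  p <- ggplot2::ggplot()
  if (nrow(object$bursts) > 0) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(object$bursts),
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0.5, ymax = object$n_electrodes + 0.5),
      fill = "grey85"
    )
  }
  p +
    ggplot2::geom_point(data = spikes,
                        ggplot2::aes(x = .data$time, y = .data$electrode),
                        shape = "|", size = 2) +
    ggplot2::scale_y_continuous(breaks = seq_len(object$n_electrodes)) +
    ggplot2::labs(x = "time (s)", y = "electrode",
                  title = sprintf("%d network bursts, NBR %.2f/min",
                                  nrow(object$bursts),
                                  object$features$NBR)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mea_analysis
#' @export
autoplot.mea_simulation <- function(object, ...) {
  autoplot.mea_analysis(analyze_simulation(object), ...)
}

#' Feature summary plot for an experiment
#'
#' Mean +/- SEM of each burst/firing feature per condition.
#'
#' @param object An `mea_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mea_experiment <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.25
    ) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± SEM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
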