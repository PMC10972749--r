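#' Plot a physiological trace with stimulus epochs
#'
#' @param trace Data frame with `time_s` and `value`.
#' @param epochs Optional epoch tibble shaded behind the trace.
#' @param downsample Keep roughly this many points for display.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, epochs = NULL, downsample = 20000) {
  check_trace_df(trace)
  if (nrow(trace) > downsample) {
    trace <- trace[seq(1, nrow(trace),
                       by = ceiling(nrow(trace) / downsample)), ]
  }
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$time_s, .data$value))
  if (!is.null(epochs) && nrow(epochs)) {
    p <- p + ggplot2::geom_rect(
      data = epochs, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$label),
      alpha = 0.2)
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "signal") +
    ggplot2::theme_minimal()
}

#' Plot segmented breaths and event calls over a trace
#'
#' Marks inspiratory onsets and overlays gasp/sigh calls from
#' [classify_events()].
#'
#' @param trace Data frame with `time_s` and `value`.
#' @param breaths Breath table from [segment_breaths()].
#' @param events Optional event table from [classify_events()].
#' @param epochs Optional epoch tibble.
#' @return A ggplot object.
#' @export
plot_breaths <- function(trace, breaths, events = NULL, epochs = NULL) {
  p <- plot_trace(trace, epochs) +
    ggplot2::geom_point(
      data = breaths, inherit.aes = FALSE,
      ggplot2::aes(x = .data$insp_onset_s, y = 0),
      shape = 3, size = 1, colour = "grey40")
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_point(
      data = events, inherit.aes = FALSE,
      ggplot2::aes(x = .data$time_s, y = 0, colour = .data$event_type),
      shape = 17, size = 2)
  }
  p
}

#' Heatmap of ratiometric dF/F0 across ROIs
#'
#' @param dff Output of [ratiometric_dff()].
#' @param epochs Optional epoch tibble marked as vertical lines.
#' @return A ggplot object.
#' @export
plot_dff_heatmap <- function(dff, epochs = NULL) {
  p <- ggplot2::ggplot(dff, ggplot2::aes(.data$time_s,
                                         factor(.data$roi),
                                         fill = .data$dff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * F / F[0])) +
    ggplot2::labs(x = "time (s)", y = "ROI") +
    ggplot2::theme_minimal()
  if (!is.null(epochs) && nrow(epochs)) {
    p <- p + ggplot2::geom_vline(xintercept = epochs$start_s,
                                 linetype = "dashed", colour = "white")
  }
  p
}

#' Bar chart of a responder tally
#'
#' @param object A [response_tally()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.response_tally <- function(object, ...) {
  d <- tidy(object)
  d$category <- factor(d$category, levels = d$category)
  ggplot2::ggplot(d, ggplot2::aes(.data$category, .data$pct)) +
    ggplot2::geom_col(fill = c("firebrick", "black", "purple", "grey70")) +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$count, "\n",
                                                   .data$pct, "%")),
                       vjust = -0.2, size = 3) +
    ggplot2::labs(x = NULL, y = "% of neurons") +
    ggplot2::theme_minimal()
}
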