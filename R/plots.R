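#' Plot a stretch of a current trace
#'
#' @param object A [current_trace()].
#' @param from_ms,to_ms Window to display, in ms from the trace start.
#' @param max_points Downsampling cap on plotted points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot current_trace
#' @export
autoplot.current_trace <- function(object, from_ms = 0,
                                   to_ms = min(80, trace_duration(object) * 1e3),
                                   max_points = 2e4, ...) {
  dt_ms <- object$sampling_interval / US_PER_MS
  i <- seq(max(1L, floor(from_ms / dt_ms)),
           min(length(object$samples), ceiling(to_ms / dt_ms)))
  if (length(i) > max_points) {
    i <- i[seq(1L, length(i), length.out = max_points)]
  }
  df <- tibble::tibble(time_ms = (i - 1L) * dt_ms, current_pa = object$samples[i])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$current_pa)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (ms)", y = "current (pA)", title = object$label) +
    ggplot2::theme_minimal()
}

#' Scatter plot of blockade level against dwell time
#'
#' The dual-parameter event display: normalized blockade on the y axis
#' against dwell time on a log x axis, optionally colored by label.
#'
#' @param events Event tibble.
#' @param color Optional column name (string) to color by, e.g. `"label"`.
#' @return A ggplot.
#' @export
plot_event_scatter <- function(events, color = NULL) {
  events <- tibble::as_tibble(events)
  events$dwell_ms <- events$dwell / US_PER_MS
  aes <- if (is.null(color)) {
    ggplot2::aes(.data$dwell_ms, .data$normalized_blockade)
  } else {
    ggplot2::aes(.data$dwell_ms, .data$normalized_blockade,
                 color = .data[[color]])
  }
  ggplot2::ggplot(events, aes) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "dwell time (ms)", y = "normalized blockade level") +
    ggplot2::theme_minimal()
}

#' Plot a blockade histogram with its fitted Gaussian components
#'
#' @param object A `blockade_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot blockade_fit
#' @export
autoplot.blockade_fit <- function(object, ...) {
  h <- object$histogram
  df <- tibble::tibble(mid = h$mids, count = as.numeric(h$counts))
  grid <- seq(min(h$bin_edges), max(h$bin_edges), length.out = 512)
  curves <- purrr::pmap_dfr(
    object$components,
    function(component, amplitude, center, width) {
      tibble::tibble(component = factor(component), x = grid,
                     y = amplitude * exp(-(grid - center)^2 / (2 * width^2)))
    })
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(width = diff(h$bin_edges[1:2]), fill = "grey80") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(.data$x, .data$y, color = .data$component)) +
    ggplot2::labs(x = "normalized blockade level", y = "events") +
    ggplot2::theme_minimal()
}

#' Plot a dwell-time histogram with its log-normal fit
#'
#' @param object A `dwell_fit`.
#' @param dwells The dwell values that were fitted (same unit as the fit).
#' @param n_bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dwell_fit
#' @export
autoplot.dwell_fit <- function(object, dwells, n_bins = 50L, ...) {
  h <- build_histogram(dwells, "dwell", n_bins)
  df <- tibble::tibble(mid = h$mids, count = as.numeric(h$counts))
  grid <- exp(seq(log(min(h$bin_edges)), log(max(h$bin_edges)),
                  length.out = 512))
  # expected counts per (log-spaced) unit, scaled to the local bin width
  widths <- approx(h$mids, diff(h$bin_edges), xout = grid, rule = 2)$y
  dens <- stats::dlnorm(grid, object$mu, max(object$sigma, 1e-9))
  curve <- tibble::tibble(x = grid, y = dens * object$n_events * widths)
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(fill = "grey80") +
    ggplot2::geom_line(data = curve, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dwell time", y = "events") +
    ggplot2::theme_minimal()
}
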