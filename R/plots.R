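#' Plotting
#'
#' `autoplot()` methods give quick ggplot2 views of traces, ratio traces,
#' onset-aligned ensembles (mean with an SD ribbon, the usual display for
#' small cell ensembles) and segmented core maps.
#'
#' @name fiberscope_plots
NULL

#' @rdname fiberscope_plots
#' @param object Object to plot.
#' @param ... Unused.
#' @method autoplot fiber_trace
#' @export
autoplot.fiber_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)",
                  y = if ("dff" %in% attr(object, "history"))
                    expression(Delta * F / F) else "intensity (counts)") +
    ggplot2::theme_minimal()
}

#' @rdname fiberscope_plots
#' @method autoplot ratio_trace
#' @export
autoplot.ratio_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "normalized ratio") +
    ggplot2::theme_minimal()
}

#' @rdname fiberscope_plots
#' @method autoplot aligned_ensemble
#' @export
autoplot.aligned_ensemble <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "time from onset (s)", y = "mean ± SD") +
    ggplot2::theme_minimal()
}

#' Plot segmented core centers over the FOV
#'
#' @param coremap A `core_map`.
#' @return A ggplot object.
#' @export
plot_coremap <- function(coremap) {
  stopifnot(inherits(coremap, "core_map"))
  df <- tibble::tibble(y = coremap$centers_px[, 1],
                       x = coremap$centers_px[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("%d cores", coremap$n_cores)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
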