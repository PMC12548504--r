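#' Plot a 2D spectrum as a filled contour map
#'
#' @param object An `hw_spectrum2d`.
#' @param n_contours Number of positive contour levels.
#' @param floor_frac Lowest contour as a fraction of the maximum intensity.
#' @param ... Unused.
#' @return A ggplot object (indirect frequency on y, direct on x, as
#'   spectra are conventionally drawn).
#' @method autoplot hw_spectrum2d
#' @export
autoplot.hw_spectrum2d <- function(object, n_contours = 12,
                                   floor_frac = 0.05, ...) {
  df <- expand.grid(f1 = object$axis1, f2 = object$axis2)
  df$intensity <- as.vector(object$intensity)
  breaks <- max(object$intensity) *
    exp(seq(log(floor_frac), 0, length.out = n_contours))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f2, y = .data$f1,
                                   z = .data$intensity)) +
    ggplot2::geom_contour(breaks = breaks,
                          ggplot2::aes(colour = ggplot2::after_stat(level))) +
    ggplot2::scale_colour_viridis_c(name = "intensity") +
    ggplot2::labs(x = "direct frequency (Hz)",
                  y = "indirect frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot the per-trace rate distribution of an estimate
#'
#' Mirrors the usual diagnostic for a common-rate assumption: a histogram
#' of the per-trace predictions with the mean marked.
#'
#' @param object An `hw_rate_estimate`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hw_rate_estimate
#' @export
autoplot.hw_rate_estimate <- function(object, bins = 15, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_rate, colour = "red") +
    ggplot2::labs(x = "predicted exogenous rate (1/s)", y = "traces",
                  subtitle = sprintf("mean %.1f 1/s, sd %.1f, n = %d",
                                     object$mean_rate, object$sd,
                                     object$n_traces)) +
    ggplot2::theme_minimal()
}

#' Plot the exogenous decay envelope
#'
#' @param object An `hw_decay_model`.
#' @param t_max Right end of the time axis in seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hw_decay_model
#' @export
autoplot.hw_decay_model <- function(object, t_max = 12.8e-3, ...) {
  t <- seq(0, t_max, length.out = 256)
  df <- data.frame(t1 = t * 1e3, E = evaluate_decay(object, t))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t1, y = .data$E)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t1 (ms)", y = "E(t1)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
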