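#' Plot a correlogram
#'
#' Bar plot of pair counts per lag bin; overlay a fitted intensity with
#' [autoplot.glmcc_fit()] or compare against [analytic_cc()] values scaled
#' by `duration * bin`.
#'
#' @param object A `correlogram` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlogram <- function(object, ...) {
  df <- tibble::tibble(lag = cc_centers(object), count = object$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_ms"), fill = "grey40") +
    ggplot2::labs(x = "lag (ms)", y = "pair count") +
    ggplot2::theme_minimal()
}

#' Plot a GLM correlogram fit
#'
#' Counts with the fitted total intensity and the background-only curve
#' `bin * exp(a(t))`; the gap between the two curves is the estimated
#' monosynaptic impact.
#'
#' @param object A `glmcc_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glmcc_fit <- function(object, ...) {
  df <- tidy(object)
  bin <- object$hyper$bin_ms
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), width = bin, fill = "grey75") +
    ggplot2::geom_line(ggplot2::aes(y = bin * exp(.data$a)), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "lag (ms)", y = "pair count",
                  title = sprintf("%s fit: J_pos = %.2f, J_neg = %.2f",
                                  object$method, object$J_pos, object$J_neg)) +
    ggplot2::theme_minimal()
}

#' Raster plot of spike trains
#'
#' @param object A `spikes` data frame.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spikes <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = factor(.data$unit))) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "unit") +
    ggplot2::theme_minimal()
}

#' Tile plot of a connection matrix
#'
#' @param object A `connection_matrix` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connection_matrix <- function(object, ...) {
  e <- edges(object)
  units <- attr(object, "units")
  ggplot2::ggplot(e, ggplot2::aes(x = factor(.data$post, levels = units),
                                  y = factor(.data$pre, levels = rev(units)),
                                  fill = .data$sign)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(excitatory = "magenta3",
                                          inhibitory = "cyan3")) +
    ggplot2::labs(x = "postsynaptic", y = "presynaptic", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
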