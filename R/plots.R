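# ggplot2 autoplot methods.

#' Plot a waveform
#'
#' @param object A `waveform`.
#' @param t_max Plot horizon, s (default warm-up plus three beats).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot waveform
#' @export
autoplot.waveform <- function(object, t_max = NULL, ...) {
  if (is.null(t_max)) t_max <- object$warmup + 3 * object$period
  tt <- seq(0, t_max, length.out = 800)
  df <- tibble::tibble(time_s = tt, velocity_m_s = wf_eval(object, tt))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$velocity_m_s)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "peak inlet velocity (m/s)")
}

#' Plot the per-iolet flow-rate series of a run
#'
#' @param object A `willis_run`.
#' @param ... Unused.
#' @return A ggplot, one line per iolet.
#' @method autoplot willis_run
#' @export
autoplot.willis_run <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(.data$time_s, .data$q_m3s, colour = .data$iolet)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(Q ~ (m^3 / s)),
                  colour = "iolet")
}

#' Plot stroke-to-healthy outlet flow ratios
#'
#' @param object A `willis_comparison`.
#' @param ... Unused.
#' @return A ggplot of the smoothed ratio series, one panel per outlet,
#'   with the unit line for reference.
#' @method autoplot willis_comparison
#' @export
autoplot.willis_comparison <- function(object, ...) {
  ggplot2::ggplot(object$ratios,
                  ggplot2::aes(.data$time_s, .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~iolet) +
    ggplot2::labs(x = "time (s)", y = "stroke / healthy flow ratio")
}
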