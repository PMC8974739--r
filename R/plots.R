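#' Plot concentration curves
#'
#' Fractional xenon concentration versus time, one line per ROI — the
#' standard presentation of sinus wash-in/wash-out measurements.
#'
#' @param conc Long tibble (`roi`, `time_s`, `c`) or `xe_concentration`.
#' @return A ggplot.
#' @export
plot_concentration_curves <- function(conc) {
  ggplot2::ggplot(conc, ggplot2::aes(x = .data$time_s, y = 100 * .data$c,
                                     colour = .data$roi)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "xenon concentration (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_concentration_curves
#' @param object An `xe_concentration`.
#' @param ... Unused.
#' @method autoplot xe_concentration
#' @export
autoplot.xe_concentration <- function(object, ...) {
  plot_concentration_curves(object)
}

#' @rdname plot_concentration_curves
#' @method autoplot xe_traces
#' @export
autoplot.xe_traces <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = 100 * .data$c,
                                       colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "simulated xenon concentration (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_concentration_curves
#' @method autoplot xe_tdc
#' @export
autoplot.xe_tdc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$hu)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "mean HU",
                  title = object$roi[[1]]) +
    ggplot2::theme_minimal()
}

#' Plot a kinetic fit over its data
#'
#' Observed window frames plus the fitted exponential, annotated with tau.
#'
#' @param object An `xe_kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xe_kinetic_fit
#' @export
autoplot.xe_kinetic_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s, y = 100 * .data$c)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (s)", y = "xenon concentration (%)",
                  title = sprintf("%s %s%s", object$roi_name, object$direction,
                                  if (object$converged)
                                    sprintf(": tau = %.2f s", object$tau_s)
                                  else " (not converged)")) +
    ggplot2::theme_minimal()
  if (object$converged) {
    tt <- seq(min(dat$time_s), max(dat$time_s), length.out = 100)
    anchor <- if (object$direction == "wash_in") {
      dat$c[which.min(abs(dat$time_s - object$t0))]
    } else object$level
    cc <- if (object$direction == "wash_in") {
      anchor + (object$level - anchor) * (1 - exp(-(tt - object$t0) / object$tau_s))
    } else {
      object$level * exp(-(tt - object$t0) / object$tau_s)
    }
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(time_s = tt, c = cc),
      ggplot2::aes(x = .data$time_s, y = 100 * .data$c),
      colour = "firebrick"
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
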