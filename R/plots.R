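# ggplot2 visualisations for correlation series, fits and trend summaries.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ensemble autocorrelation function
#'
#' Log-log plot of the ensemble mean with its standard-error ribbon and the
#' limiting value as a dashed horizontal line.
#'
#' @param object a `correlation_series`.
#' @param fit optional `relaxation_fit` overlaid as a dotted curve.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_series <- function(object, fit = NULL, ...) {
  dat <- dplyr::filter(object, .data$time_ps > 0)
  lab <- if (identical(attr(object, "kind"), "energy")) {
    c(expression(C[E](t) ~ (eV^2)))
  } else {
    c(expression(C[D](t) ~ (ring(A)^2)))
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_ps, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "t (ps)", y = lab) +
    ggplot2::theme_minimal()
  chi <- attr(object, "chi")
  if (is.finite(chi) && chi > 0) {
    p <- p + ggplot2::geom_hline(yintercept = chi, linetype = "dashed")
  }
  if (!is.null(fit)) {
    t_ns <- 10^seq(log10(max(fit$t_start_ns, 1e-5)),
                   log10(max(dat$time_ps) / 1e3), length.out = 200)
    fdat <- tibble::tibble(time_ps = t_ns * 1e3,
                           mean = kww(t_ns, fit$A, fit$tau_ns, fit$beta,
                                      fit$chi))
    p <- p + ggplot2::geom_line(data = fdat, linetype = "dotted",
                                colour = "black")
  }
  p
}

#' Plot a stretched-exponential fit over its data
#'
#' @param object a `relaxation_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.relaxation_fit <- function(object, ...) {
  dat <- object$data
  t_ns <- 10^seq(log10(min(dat$time_ns)), log10(max(dat$time_ns)),
                 length.out = 200)
  curve <- tibble::tibble(
    time_ns = t_ns,
    value = kww(t_ns, object$A, object$tau_ns, object$beta, object$chi))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_ns, y = .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = object$chi, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "t (ns)", y = "C(t)",
                  subtitle = sprintf("tau_av = %.3g ns, beta = %.2f",
                                     object$tau_av_ns, object$beta)) +
    ggplot2::theme_minimal()
}

#' Average relaxation time versus bubble amplitude
#'
#' One point per (w, h) cell of an experiment, coloured by width, with the
#' per-width linear trends overlaid.
#'
#' @param x an `experiment_result`.
#' @return A ggplot object.
#' @export
plot_tau_av <- function(x) {
  fits <- dplyr::mutate(x$fits, width = factor(.data$w))
  p <- ggplot2::ggplot(fits, ggplot2::aes(x = .data$h, y = .data$tau_av_ns,
                                          colour = .data$width)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$tau_av_ns - .data$tau_av_sd,
                                        ymax = .data$tau_av_ns + .data$tau_av_sd),
                           width = 0.05) +
    ggplot2::labs(x = "h (Å)", y = expression(tau[av] ~ (ns)),
                  colour = "w (bp)") +
    ggplot2::theme_minimal()
  if (!is.null(x$trends)) {
    lines <- dplyr::bind_rows(purrr::map(x$trends, function(t) {
      hs <- range(x$fits$h)
      tibble::tibble(h = hs, tau_av_ns = t$tau0 + t$alpha * hs,
                     width = factor(t$width))
    }))
    p <- p + ggplot2::geom_line(data = lines)
  }
  p
}
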