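# Stretched-exponential (KWW) relaxation fits, average relaxation times,
# bootstrap uncertainties and amplitude/width trend fits.

kww <- function(t_ns, A, tau_ns, beta, chi) {
  A * exp(-(t_ns / tau_ns)^beta) + chi
}

# summary.lm warns on zero-residual data; harmless for exact synthetic lines
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Automatic fit-window start
#'
#' Returns the earliest recorded time after which the (median-smoothed)
#' correlation series has entered the monotone rapid-decay stage, i.e. past
#' the initial oscillations. The series mean is smoothed with a running
#' median over `k` log-grid points; the start is the earliest time from which
#' the smoothed series never increases by more than `noise_mult` times the
#' median SEM between consecutive points.
#'
#' @param series a `correlation_series`.
#' @param k running-median window (odd, default 5 grid points).
#' @param noise_mult tolerated rise between consecutive smoothed points, in
#'   units of the standard error of their difference (default 2; 0 demands
#'   strict monotonicity). Coherent early oscillations rise by much more
#'   than the ensemble SEM and are excluded; incoherent tail noise is not.
#' @param skip_ps ignore times earlier than this when searching (default:
#'   the second grid point, so the t = 0 anchor never truncates the search).
#' @return Fit-window start in ns.
#' @export
select_fit_start <- function(series, k = 5, noise_mult = 2, skip_ps = NULL) {
  t_ps <- series$time_ps
  m <- stats::runmed(series$mean, k, endrule = "median")
  sem <- series$sem
  if (!all(is.finite(sem))) sem <- rep(0, length(m))
  d <- diff(m)
  # viol[i]: smoothed series rises between grid points i, i+1 by more than
  # noise_mult standard errors of the difference of two ensemble means
  tol <- noise_mult * sqrt(sem[-length(sem)]^2 + sem[-1]^2)
  viol <- d > tol
  last_viol <- if (any(viol)) max(which(viol)) else 0
  start_idx <- last_viol + 1
  if (!is.null(skip_ps)) start_idx <- max(start_idx, which(t_ps >= skip_ps)[1])
  if (start_idx > length(t_ps) - 9) {
    rlang::abort(paste("no monotone decay tail with >= 10 points found;",
                       "run longer or override t_start"))
  }
  t_ps[start_idx] / 1e3
}

#' Fit a stretched exponential to a correlation series
#'
#' Weighted nonlinear least squares of
#' `C(t) = A exp(-(t / tau)^beta) + chi` to the recorded points with
#' `t >= t_start` (and, optionally, `t <= t_end`). The asymptote `chi` is
#' fixed at the limiting value of the autocorrelation function (it is not a
#' free parameter); `A`, `tau` and `beta` are free. Weights are `1 / sem^2`
#' where SEMs are available and positive, otherwise uniform.
#'
#' The KWW objective is multimodal on noisy, decade-limited data: a
#' degenerate ridge at very small `beta` (an almost-flat power-law-like
#' tail) can undercut the physical optimum. Three safeguards address this:
#' the optimiser is restarted from a small grid of `(tau, beta)` initial
#' values and the lowest weighted-SSE solution kept; `beta` is bounded
#' below by `beta_range[1]` (default 0.3 — fitted exponents for these
#' relaxations sit well above it, and smaller values imply implausibly
#' broad relaxation-time distributions); and `A` is capped at three times
#' the amplitude remaining at the window start. All three are overridable.
#'
#' @param series a `correlation_series` (times in ps).
#' @param t_start_ns fit-window start (ns); default via [select_fit_start()].
#' @param chi fixed asymptote; defaults to the series' `chi` attribute.
#' @param t_end_ns optional fit-window end (ns); see [select_fit_end()] for
#'   truncating noisy post-convergence tails.
#' @param beta_range allowed range of the stretched exponent.
#' @param multistart restart from a grid of initial values (default TRUE);
#'   `FALSE` uses the single classic start (`A = C(t_start) - chi`, `tau`
#'   at the 1/e crossing, `beta = 0.7`).
#' @return An object of class `relaxation_fit`: fields `A`, `tau_ns`, `beta`,
#'   `chi`, `t_start_ns`, `t_end_ns`, `tau_av_ns`, `kind`, `n_points`, and
#'   (after [bootstrap_uncertainty()]) a `se` list.
#' @export
fit_stretched_exponential <- function(series, t_start_ns = NULL, chi = NULL,
                                      t_end_ns = NULL,
                                      beta_range = c(0.3, 2),
                                      multistart = TRUE) {
  chi <- chi %||% attr(series, "chi")
  if (is.null(chi) || !is.finite(chi)) {
    rlang::abort("a finite fixed asymptote `chi` is required")
  }
  t_start_ns <- t_start_ns %||% select_fit_start(series)
  dat <- dplyr::filter(series, .data$time_ps >= t_start_ns * 1e3)
  if (!is.null(t_end_ns)) {
    dat <- dplyr::filter(dat, .data$time_ps <= t_end_ns * 1e3)
  }
  if (nrow(dat) < 10) {
    rlang::abort(sprintf("only %d points in [%g, %g] ns; need >= 10",
                         nrow(dat), t_start_ns, t_end_ns %||% Inf))
  }
  t_ns <- dat$time_ps / 1e3
  C <- dat$mean
  wts <- if (all(is.finite(dat$sem)) && all(dat$sem > 0)) {
    1 / dat$sem^2
  } else {
    rep(1, nrow(dat))
  }

  A0 <- max(C[1] - chi, 1e-12)
  below <- which(C - chi <= A0 / exp(1))
  tau0 <- if (length(below) > 0) t_ns[below[1]] else t_ns[length(t_ns)] / 2
  tau0 <- max(tau0, 1e-6)

  starts <- list(list(A = A0, tau = tau0, beta = 0.7))
  if (multistart) {
    tmax <- max(t_ns)
    tau_grid <- exp(seq(log(max(tmax / 100, 1e-6)), log(2 * tmax),
                        length.out = 4))
    for (tg in tau_grid) {
      for (bg in c(0.4, 0.8, 1.2)) {
        starts <- c(starts, list(list(A = A0, tau = tg, beta = bg)))
      }
    }
  }

  one_fit <- function(st) {
    st$beta <- min(max(st$beta, beta_range[1]), beta_range[2])
    tryCatch(suppressWarnings(minpack.lm::nlsLM(
      C ~ A * exp(-(t_ns / tau)^beta) + chi,
      data = data.frame(t_ns = t_ns, C = C),
      start = st,
      lower = c(A = 0, tau = 1e-9, beta = beta_range[1]),
      upper = c(A = 3 * A0, tau = Inf, beta = beta_range[2]),
      weights = wts,
      control = minpack.lm::nls.lm.control(maxiter = 300)
    )), error = function(e) NULL)
  }
  fits <- purrr::compact(purrr::map(starts, one_fit))
  if (length(fits) == 0) {
    rlang::abort(sprintf(
      "stretched-exponential fit failed from all starts; initial guesses A=%.3g, tau=%.3g ns",
      A0, tau0))
  }
  sse <- vapply(fits, function(f) sum(wts * stats::residuals(f)^2),
                numeric(1))
  fit <- fits[[which.min(sse)]]
  cf <- stats::coef(fit)
  if (!all(is.finite(cf))) rlang::abort("fit returned non-finite parameters")
  structure(list(A = unname(cf["A"]), tau_ns = unname(cf["tau"]),
                 beta = unname(cf["beta"]), chi = chi,
                 t_start_ns = t_start_ns, t_end_ns = t_end_ns,
                 beta_range = beta_range, multistart = multistart,
                 tau_av_ns = tau_average(unname(cf["tau"]), unname(cf["beta"])),
                 kind = attr(series, "kind") %||% "unknown",
                 n_points = nrow(dat),
                 se = NULL,
                 data = tibble::tibble(time_ns = t_ns, value = C,
                                       weight = wts)),
            class = "relaxation_fit")
}

#' Fit-window end beyond which a converged tail is only noise
#'
#' Once the ensemble mean has reached its limiting value, later points
#' carry no information about the decay but plenty of ensemble noise (a
#' single realisation with a long-lived localised structure can hold a
#' small ensemble's tail above `chi` for many nanoseconds). This returns
#' the first time after `t_start_ns` at which the median-smoothed series
#' drops to within `touch_mult` median-SEMs of `chi` — or `NULL` (no
#' truncation) if it never converges within the record.
#'
#' @param series a `correlation_series`.
#' @param chi limiting value (defaults to the series attribute).
#' @param t_start_ns fit-window start (ns).
#' @param touch_mult convergence margin in units of the median SEM.
#' @param k running-median window (odd).
#' @return Fit-window end in ns, or `NULL`.
#' @export
select_fit_end <- function(series, chi = NULL, t_start_ns = 0,
                           touch_mult = 0.5, k = 5) {
  chi <- chi %||% attr(series, "chi")
  if (is.null(chi) || !is.finite(chi)) rlang::abort("finite chi required")
  m <- stats::runmed(series$mean, k, endrule = "median")
  t_ns <- series$time_ps / 1e3
  margin <- touch_mult * stats::median(series$sem[is.finite(series$sem)],
                                       na.rm = TRUE)
  if (!is.finite(margin)) margin <- 0
  touch <- which(t_ns > t_start_ns & m <= chi + margin)[1]
  if (is.na(touch)) NULL else t_ns[touch]
}

#' Average relaxation time of a stretched exponential
#'
#' `tau_av = Gamma(1 / beta) / beta * tau`, the mean of the underlying
#' relaxation-time distribution; equals the integral of
#' `exp(-(t / tau)^beta)` over `t` in `[0, Inf)`.
#'
#' @param tau characteristic time (ns), or a `relaxation_fit` object.
#' @param beta stretched exponent (ignored when `tau` is a fit object).
#' @return Average relaxation time in the units of `tau`.
#' @export
tau_average <- function(tau, beta = NULL) {
  if (inherits(tau, "relaxation_fit")) {
    beta <- tau$beta
    tau <- tau$tau_ns
  }
  if (is.null(beta) || any(beta <= 0)) rlang::abort("beta must be > 0")
  gamma(1 / beta) / beta * tau
}

#' @export
print.relaxation_fit <- function(x, ...) {
  se <- x$se
  fmt <- function(v, s) {
    if (is.null(s)) sprintf("%.4g", v) else format_uncertainty(v, s)
  }
  cat(sprintf(
    "<relaxation_fit> %s: A=%s, tau=%s ns, beta=%s, chi=%.4g (fixed), tau_av=%s ns [t_start=%.3g ns, %d pts]\n",
    x$kind, fmt(x$A, se$A), fmt(x$tau_ns, se$tau_ns), fmt(x$beta, se$beta),
    x$chi, fmt(x$tau_av_ns, se$tau_av_ns), x$t_start_ns, x$n_points))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.relaxation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "tau_ns", "beta", "tau_av_ns"),
    estimate = c(x$A, x$tau_ns, x$beta, x$tau_av_ns),
    std.error = c(x$se$A %||% NA_real_, x$se$tau_ns %||% NA_real_,
                  x$se$beta %||% NA_real_, x$se$tau_av_ns %||% NA_real_)
  )
}

#' @export
#' @importFrom generics glance
glance.relaxation_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, chi = x$chi, t_start_ns = x$t_start_ns,
                 tau_av_ns = x$tau_av_ns, n_points = x$n_points)
}

#' Bootstrap uncertainties for a stretched-exponential fit
#'
#' Resamples realisations (columns of the per-run matrix carried by the
#' correlation series) with replacement, rebuilds the ensemble mean curve,
#' refits the stretched exponential with the same fixed `chi` and `t_start`,
#' and reports the standard deviation of each parameter and of `tau_av`
#' across resamples. Errors if more than 10% of the refits fail.
#'
#' @param series a `correlation_series` carrying its `per_run` matrix.
#' @param fit a `relaxation_fit` of `series` (fixes `chi` and `t_start`).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed for resampling.
#' @return The `fit` with its `se` field filled
#'   (`A`, `tau_ns`, `beta`, `tau_av_ns`), plus attribute `boot` holding the
#'   resampled parameter tibble.
#' @export
bootstrap_uncertainty <- function(series, fit, n_boot = 1000, seed = 1) {
  per_run <- attr(series, "per_run")
  if (is.null(per_run)) rlang::abort("series carries no per-run matrix")
  n_runs <- ncol(per_run)
  set.seed(seed)
  draws <- matrix(sample.int(n_runs, n_runs * n_boot, replace = TRUE),
                  nrow = n_runs)
  res <- purrr::map(seq_len(n_boot), function(bb) {
    cols <- draws[, bb]
    bser <- new_correlation_series(series$time_ps,
                                   per_run[, cols, drop = FALSE],
                                   attr(series, "kind"), fit$chi)
    tryCatch({
      bf <- fit_stretched_exponential(bser, t_start_ns = fit$t_start_ns,
                                      chi = fit$chi,
                                      t_end_ns = fit$t_end_ns,
                                      beta_range = fit$beta_range %||% c(0.3, 2),
                                      multistart = fit$multistart %||% TRUE)
      c(A = bf$A, tau_ns = bf$tau_ns, beta = bf$beta,
        tau_av_ns = bf$tau_av_ns)
    }, error = function(e) NULL)
  })
  ok <- !vapply(res, is.null, logical(1))
  if (mean(ok) < 0.9) {
    rlang::abort(sprintf("%.0f%% of bootstrap refits failed",
                         100 * mean(!ok)))
  }
  boot <- dplyr::bind_rows(purrr::map(res[ok], ~ tibble::as_tibble(as.list(.x))))
  fit$se <- as.list(vapply(boot, stats::sd, numeric(1)))
  fit$n_boot <- sum(ok)
  attr(fit, "boot") <- boot
  fit
}

#' Linear dependence of the relaxation time on bubble amplitude
#'
#' Fits `tau_av = tau0 + alpha h` across amplitudes at a fixed bubble width,
#' by weighted least squares with weights `1 / sd^2` when uncertainties are
#' supplied (reducing to ordinary least squares when they are equal or
#' absent).
#'
#' @param data a data frame with columns `h` (A), `tau_av` (ns) and
#'   optionally `tau_av_sd`; at least 3 distinct amplitudes.
#' @param width the bubble width (bp) the amplitudes share.
#' @return An object of class `trend_fit` with fields `tau0`, `alpha`,
#'   `tau0_sd`, `alpha_sd`, `width`, `n`.
#' @export
amplitude_linear_fit <- function(data, width) {
  stopifnot(all(c("h", "tau_av") %in% names(data)))
  if (length(unique(data$h)) < 3) {
    rlang::abort("need >= 3 distinct amplitudes for the linear trend")
  }
  w <- if ("tau_av_sd" %in% names(data) &&
             all(is.finite(data$tau_av_sd)) && all(data$tau_av_sd > 0)) {
    1 / data$tau_av_sd^2
  } else {
    rep(1, nrow(data))
  }
  fm <- stats::lm(tau_av ~ h, data = data, weights = w)
  cf <- stats::coef(fm)
  se <- sqrt(diag(quiet_perfect_fit(stats::vcov(fm))))
  structure(list(tau0 = unname(cf[1]), alpha = unname(cf[2]),
                 tau0_sd = unname(se[1]), alpha_sd = unname(se[2]),
                 width = width, n = nrow(data)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> w=%g bp: tau_av = %s + %s h  (ns, h in A)\n",
              x$width, format_uncertainty(x$tau0, x$tau0_sd),
              format_uncertainty(x$alpha, x$alpha_sd)))
  invisible(x)
}

#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(term = c("tau0", "alpha"),
                 estimate = c(x$tau0, x$alpha),
                 std.error = c(x$tau0_sd, x$alpha_sd),
                 width = x$width)
}

#' Width dependence of the amplitude-trend coefficients
#'
#' Given per-width amplitude trends (`tau_av = tau0(w) + alpha(w) h`), fits
#' straight lines `tau0 = s0 w + i0` and `alpha = s1 w + i1`, composing the
#' closed-form relaxation-time map
#' `tau_av(w, h) = (s0 w + i0) + (s1 w + i1) h`.
#'
#' @param trends a list of `trend_fit`s (or a tibble from their `tidy()`
#'   rows) covering at least 3 distinct widths.
#' @return An object of class `width_trend` with elements `tau0_line` and
#'   `alpha_line` (each `intercept`, `slope`, `intercept_sd`, `slope_sd`)
#'   and a `predict(w, h)` closure.
#' @export
width_trend_fit <- function(trends) {
  if (is.list(trends) && inherits(trends[[1]], "trend_fit")) {
    tab <- dplyr::bind_rows(purrr::map(trends, function(t) {
      tibble::tibble(width = t$width, tau0 = t$tau0, tau0_sd = t$tau0_sd,
                     alpha = t$alpha, alpha_sd = t$alpha_sd)
    }))
  } else {
    tab <- tibble::as_tibble(trends)
  }
  if (length(unique(tab$width)) < 3) {
    rlang::abort("need >= 3 distinct widths")
  }
  line_fit <- function(y, sd) {
    w <- if (all(is.finite(sd)) && all(sd > 0)) 1 / sd^2 else rep(1, length(y))
    fm <- stats::lm(y ~ tab$width, weights = w)
    cf <- stats::coef(fm)
    se <- sqrt(diag(quiet_perfect_fit(stats::vcov(fm))))
    list(intercept = unname(cf[1]), slope = unname(cf[2]),
         intercept_sd = unname(se[1]), slope_sd = unname(se[2]))
  }
  tau0_line <- line_fit(tab$tau0, tab$tau0_sd %||% rep(NA_real_, nrow(tab)))
  alpha_line <- line_fit(tab$alpha, tab$alpha_sd %||% rep(NA_real_, nrow(tab)))
  structure(list(
    tau0_line = tau0_line, alpha_line = alpha_line, table = tab,
    predict = function(w, h) {
      (tau0_line$intercept + tau0_line$slope * w) +
        (alpha_line$intercept + alpha_line$slope * w) * h
    }
  ), class = "width_trend")
}

#' @export
print.width_trend <- function(x, ...) {
  cat(sprintf(
    "<width_trend> tau0(w) = %s w + %s ns;  alpha(w) = %s w + %s ns/A\n",
    format_uncertainty(x$tau0_line$slope, x$tau0_line$slope_sd),
    format_uncertainty(x$tau0_line$intercept, x$tau0_line$intercept_sd),
    format_uncertainty(x$alpha_line$slope, x$alpha_line$slope_sd),
    format_uncertainty(x$alpha_line$intercept, x$alpha_line$intercept_sd)))
  invisible(x)
}

#' @export
tidy.width_trend <- function(x, ...) {
  tibble::tibble(
    line = rep(c("tau0", "alpha"), each = 2),
    term = rep(c("intercept", "slope"), 2),
    estimate = c(x$tau0_line$intercept, x$tau0_line$slope,
                 x$alpha_line$intercept, x$alpha_line$slope),
    std.error = c(x$tau0_line$intercept_sd, x$tau0_line$slope_sd,
                  x$alpha_line$intercept_sd, x$alpha_line$slope_sd)
  )
}

#' Compact parenthesis notation for a value with uncertainty
#'
#' Rounds the uncertainty to one significant figure, the value to the same
#' decimal place, and prints the uncertainty digit in parentheses:
#' `format_uncertainty(0.238, 0.082)` gives `"0.24(8)"`.
#'
#' @param value,sd the estimate and its standard uncertainty.
#' @return A character scalar.
#' @export
format_uncertainty <- function(value, sd) {
  if (is.null(sd) || !is.finite(sd) || sd <= 0) {
    return(sprintf("%.4g", value))
  }
  expo <- floor(log10(sd))
  sd1 <- round(sd / 10^expo) # 1..10
  if (sd1 == 10) {
    sd1 <- 1
    expo <- expo + 1
  }
  if (expo <= 0) {
    digits <- -expo
    sprintf("%.*f(%d)", digits, round(value, digits), sd1)
  } else {
    sprintf("%.0f(%.0f)", round(value / 10^expo) * 10^expo, sd1 * 10^expo)
  }
}
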