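# Ensemble autocorrelation functions over the bubble window.
#
# The estimators are the raw (non-normalised) t = 0-anchored products
#   C_D(t) = < (1/w) sum_i y_i(0) y_i(t) >,
#   C_E(t) = < (1/w) sum_i eps_i(0) eps_i(t) >,
# averaged over the ensemble of realisations, with no mean subtraction or
# variance normalisation: only in this raw form do the limiting values
# chi_D = < (1/w) sum_i y_i(0) > y_eq and chi_E = < (1/w) sum_i eps_i(0) > eps_eq
# make sense as long-time asymptotes.

new_correlation_series <- function(times_ps, per_run, kind, chi = NA_real_) {
  n_runs <- ncol(per_run)
  mean_v <- rowMeans(per_run)
  sem <- if (n_runs >= 2) {
    apply(per_run, 1, stats::sd) / sqrt(n_runs)
  } else {
    rep(NA_real_, nrow(per_run))
  }
  out <- tibble::tibble(time_ps = times_ps, mean = mean_v, sem = sem)
  structure(out, per_run = per_run, kind = kind, chi = chi, n_runs = n_runs,
            class = c("correlation_series", class(out)))
}

check_shared_grid <- function(results) {
  times <- results[[1]]$record$times_ps
  ok <- vapply(results, function(r) {
    length(r$record$times_ps) == length(times) &&
      all(r$record$times_ps == times)
  }, logical(1))
  if (!all(ok)) rlang::abort("realisations do not share a recording grid")
  times
}

per_run_matrix <- function(results, field) {
  w <- length(results[[1]]$record$window)
  vapply(results, function(r) {
    M <- r$record[[field]]
    as.vector(M %*% M[1, ]) / w
  }, numeric(length(results[[1]]$record$times_ps)))
}

#' Ensemble displacement autocorrelation over the bubble window
#'
#' For each realisation computes `(1/w) sum_i y_i(0) y_i(t)` over the bubble
#' window, then averages across the ensemble; the uncertainty band is the
#' standard deviation of the mean. The limiting value `chi_D`, computed via
#' [limiting_chi()], is attached as an attribute.
#'
#' @param results a list of `realisation_result`s sharing the recording grid
#'   and window.
#' @param y_eq equilibrium mean displacement (A); defaults to the average of
#'   the realisations' pre-insertion chain means.
#' @return A `correlation_series` tibble (`time_ps`, `mean`, `sem`; units
#'   A^2) with attributes `chi`, `kind = "displacement"`, `n_runs`, and the
#'   `per_run` matrix.
#' @export
displacement_autocorrelation <- function(results, y_eq = NULL) {
  times <- check_shared_grid(results)
  M <- per_run_matrix(results, "Y")
  chi <- limiting_chi(results, kind = "displacement", y_eq = y_eq)
  new_correlation_series(times, M, "displacement", chi)
}

#' Ensemble energy autocorrelation over the bubble window
#'
#' Same estimator as [displacement_autocorrelation()] applied to the local
#' energies per base pair.
#'
#' @inheritParams displacement_autocorrelation
#' @param epsilon_eq equilibrium energy per base pair (eV); defaults to the
#'   realisations' configured energy per site.
#' @return A `correlation_series` tibble (units eV^2) with `chi` attached.
#' @export
energy_autocorrelation <- function(results, epsilon_eq = NULL) {
  times <- check_shared_grid(results)
  M <- per_run_matrix(results, "E")
  chi <- limiting_chi(results, kind = "energy", epsilon_eq = epsilon_eq)
  new_correlation_series(times, M, "energy", chi)
}

#' Limiting (asymptotic) value of an autocorrelation function
#'
#' `chi = < (1/w) sum_i x_i(0) x_eq >`: the ensemble average of the window
#' initial values times the equilibrium value of the observable. For
#' displacements, `x_eq` is the thermal mean displacement of the whole chain
#' (estimated from the pre-insertion tail averages of all runs); for local
#' energies it is the configured energy per base pair, since microcanonical
#' evolution fixes the mean local energy at its initial value.
#'
#' @inheritParams displacement_autocorrelation
#' @param kind `"displacement"` or `"energy"`.
#' @param epsilon_eq equilibrium energy per base pair (eV), energy kind only.
#' @return The limiting value (A^2 or eV^2).
#' @export
limiting_chi <- function(results, kind = c("displacement", "energy"),
                         y_eq = NULL, epsilon_eq = NULL) {
  kind <- match.arg(kind)
  if (kind == "displacement") {
    if (is.null(y_eq)) {
      pre <- vapply(results, function(r) r$pre_insertion_mean_y %||% NA_real_,
                    numeric(1))
      if (anyNA(pre)) {
        rlang::abort("pre-insertion mean displacements missing: cannot estimate y_eq")
      }
      y_eq <- mean(pre)
    }
    vals <- vapply(results, function(r) mean(r$y0_window) * y_eq, numeric(1))
  } else {
    if (is.null(epsilon_eq)) {
      epsilon_eq <- results[[1]]$energy_per_site
    }
    vals <- vapply(results, function(r) mean(r$e0_window) * epsilon_eq,
                   numeric(1))
  }
  mean(vals)
}

#' Ensemble mean and standard error from per-run series
#'
#' Combines per-run correlation curves (one column per realisation) into a
#' `correlation_series` with the ensemble mean and the standard deviation of
#' the mean at each time.
#'
#' @param per_run numeric matrix, `length(times_ps)` rows by `n_runs >= 2`
#'   columns.
#' @param times_ps recording times (ps).
#' @param kind observable label.
#' @param chi limiting value to attach.
#' @return A `correlation_series` tibble.
#' @export
ensemble_stats <- function(per_run, times_ps, kind = "energy",
                           chi = NA_real_) {
  per_run <- as.matrix(per_run)
  if (ncol(per_run) < 2) {
    rlang::abort("need at least 2 runs for a standard error of the mean")
  }
  stopifnot(nrow(per_run) == length(times_ps))
  new_correlation_series(times_ps, per_run, kind, chi)
}
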