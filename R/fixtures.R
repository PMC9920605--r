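# Synthetic fixtures with known ground truth: noisy stretched-exponential
# ensembles for the fitting stage, analytic phonon initial conditions for
# the integrator, and a scaled-down end-to-end mini ensemble.

#' Synthetic stretched-exponential ensemble
#'
#' Generates `n_runs` noisy realisations of the curve
#' `A exp(-(t / tau)^beta) + chi` on a log time grid. The per-run noise is
#' AR(1)-correlated along time (lag-1 correlation 0.5, marginal standard
#' deviation `noise_scale`), emulating the smooth per-run autocorrelation
#' curves of real ensembles: independent noise would make the fitting
#' problem unrealistically easy.
#'
#' @param A,tau_ns,beta,chi true stretched-exponential parameters
#'   (`tau_ns > 0`, `0 < beta <= 2`).
#' @param n_runs ensemble size.
#' @param noise_scale marginal noise standard deviation (same units as `A`).
#' @param seed RNG seed (the fixture is a pure function of it).
#' @param times_ps recording grid in ps (default: log grid over 0.01 ps to
#'   100 ns, 50 points per decade).
#' @return A `kww_fixture` / `correlation_series` tibble with attributes
#'   `per_run`, `chi` and `true_params`.
#' @export
synth_kww_ensemble <- function(A, tau_ns, beta, chi, n_runs = 200,
                               noise_scale = 0, seed = 1,
                               times_ps = log_time_grid(1e5)) {
  stopifnot(tau_ns > 0, beta > 0, beta <= 2, noise_scale >= 0, n_runs >= 1)
  set.seed(seed)
  truth <- kww(times_ps / 1e3, A, tau_ns, beta, chi)
  nt <- length(times_ps)
  per_run <- vapply(seq_len(n_runs), function(r) {
    if (noise_scale == 0) return(truth)
    eps <- numeric(nt)
    eps[1] <- stats::rnorm(1)
    innov <- stats::rnorm(nt - 1, sd = sqrt(1 - 0.5^2))
    for (k in 2:nt) eps[k] <- 0.5 * eps[k - 1] + innov[k - 1]
    truth + noise_scale * eps
  }, numeric(nt))
  out <- new_correlation_series(times_ps, per_run, "energy", chi)
  attr(out, "true_params") <- list(A = A, tau_ns = tau_ns, beta = beta,
                                   chi = chi, noise_scale = noise_scale)
  class(out) <- c("kww_fixture", class(out))
  out
}

#' Phonon (plane-wave) initial condition and its analytic frequency
#'
#' Builds the small-amplitude plane wave `y_n = amplitude * cos(q n)` on a
#' periodic chain together with the linearised dispersion frequency
#' `omega(q)^2 = (2 D a^2 + 2 K (1 + rho) (1 - cos q)) / m` (internal time
#' units), obtained by expanding the Morse and stacking potentials about
#' `y = 0`. Amplitudes above 0.01 A leave the linear regime and trigger a
#' warning.
#'
#' @param params a [pbd_params()].
#' @param q wavenumber in radians per site; `q = 2 pi k / N` is commensurate
#'   with the periodic chain.
#' @param amplitude plane-wave amplitude (A).
#' @param n_sites chain length.
#' @return A list with `state` (a [chain_state()]), `omega` (rad per
#'   internal time unit), `freq_per_ps` and `period_ps`.
#' @export
phonon_fixture <- function(params, q, amplitude = 0.005, n_sites = 16) {
  if (amplitude > 0.01) {
    warning("amplitude > 0.01 A: anharmonic corrections will shift the frequency")
  }
  y <- amplitude * cos(q * seq_len(n_sites))
  omega2 <- (2 * params$D * params$a^2 +
               2 * params$K * (1 + params$rho) * (1 - cos(q))) / params$mass
  omega <- sqrt(omega2)
  list(state = chain_state(y, rep(0, n_sites)),
       omega = omega,
       freq_per_ps = omega / (pbd_constants$time_unit_fs * 1e-3),
       period_ps = 2 * pi / omega * pbd_constants$time_unit_fs * 1e-3)
}

#' Scaled-down end-to-end ensemble
#'
#' Runs the full protocol (initialise, thermalise, insert bubble, record) at
#' reduced duration and ensemble size, for smoke tests and desk-scale
#' studies: defaults are N = 300, 0.5 ns thermalisation and 2 ns
#' post-insertion recording.
#'
#' @param params a [pbd_params()].
#' @param spec a [bubble_spec()].
#' @param n_runs ensemble size (>= 2).
#' @param seed master seed; per-realisation seeds are drawn from it and
#'   recorded on the results.
#' @param thermalisation_ns,post_ns stage durations (ns).
#' @param cfg an [integrator_config()].
#' @return A list of `realisation_result`s.
#' @export
mini_ensemble <- function(params, spec, n_runs = 4, seed = 1,
                          thermalisation_ns = 0.5, post_ns = 2,
                          cfg = integrator_config()) {
  stopifnot(n_runs >= 2)
  seeds <- derive_seeds(seed, n_runs)
  purrr::map(seeds, function(s) {
    run_realisation(params, cfg, spec, seed = s, post_ns = post_ns,
                    thermalisation_ns = thermalisation_ns)
  })
}

# Counter-based expansion of a master seed into per-realisation seeds,
# recorded in manifests/results so any single run can be reproduced alone.
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
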