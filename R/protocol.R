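# Bubble-insertion protocol: random-momentum microcanonical initialisation,
# thermalisation, Gaussian bubble insertion with bisection energy rescaling,
# and full recorded realisations.

#' Gaussian bubble specification
#'
#' An out-of-equilibrium opening imposed on `w` consecutive base pairs:
#' displacements in the bubble region are replaced by the Gaussian
#' `y(x) = h exp(-(x - c)^2 / (2 sigma^2))` with `sigma = w / 6`, so the
#' bubble tails sit at near-equilibrium displacement (edge sites lie 3 sigma
#' from the centre).
#'
#' @param h bubble amplitude (A).
#' @param w bubble width in base pairs; odd, `3 <= w < n_sites`.
#' @param n_sites chain length N (default 300).
#' @param centre centre site `c` (1-based); defaults to `N / 2`, placing the
#'   bubble region at sites `(N - w + 1) / 2 .. (N + w - 1) / 2`.
#' @return An object of class `bubble_spec` with fields `h`, `w`, `centre`,
#'   `sigma` and the 1-based `sites` of the bubble region.
#' @export
bubble_spec <- function(h, w, n_sites = 300, centre = n_sites / 2) {
  stopifnot(h > 0, w >= 3, w %% 2 == 1, w < n_sites)
  half <- (w - 1) / 2
  sites <- seq(centre - half, centre + half)
  stopifnot(all(sites >= 1), all(sites <= n_sites))
  structure(list(h = h, w = as.integer(w), centre = centre,
                 sigma = w / 6, n_sites = as.integer(n_sites),
                 sites = as.integer(sites)),
            class = "bubble_spec")
}

#' @export
print.bubble_spec <- function(x, ...) {
  cat(sprintf("<bubble_spec> h=%g A, w=%d bp (sigma=%.3g), centre=%g, sites %d..%d\n",
              x$h, x$w, x$sigma, x$centre, min(x$sites), max(x$sites)))
  invisible(x)
}

#' Evaluate the Gaussian bubble profile
#'
#' @param spec a [bubble_spec()].
#' @param sites 1-based site indices at which to evaluate (default: the
#'   bubble region).
#' @return Displacements in A.
#' @export
bubble_profile <- function(spec, sites = spec$sites) {
  spec$h * exp(-(sites - spec$centre)^2 / (2 * spec$sigma^2))
}

#' Microcanonical initial state
#'
#' All displacements at equilibrium (`y = 0`); momenta drawn from a zero-mean
#' normal distribution and rescaled by a single factor so that the total
#' energy is exactly `N * energy_per_site` (all of it kinetic at t = 0).
#'
#' @param n_sites chain length N.
#' @param energy_per_site target energy per base pair (eV).
#' @param seed integer RNG seed (realisation identity).
#' @param params a [pbd_params()] (supplies the mass).
#' @return A [chain_state()].
#' @export
initial_state <- function(n_sites, energy_per_site, seed, params) {
  stopifnot(energy_per_site >= 0)
  set.seed(seed)
  p <- stats::rnorm(n_sites)
  while (all(p == 0)) p <- stats::rnorm(n_sites)
  if (energy_per_site == 0) {
    p <- rep(0, n_sites)
  } else {
    p <- p * sqrt(2 * params$mass * n_sites * energy_per_site / sum(p^2))
  }
  chain_state(rep(0, n_sites), p)
}

#' Thermalise a chain
#'
#' Evolves the state for `duration_ns` (default 10 ns) so the initial
#' all-kinetic energy redistributes over the lattice. The chain-mean
#' displacement and kinetic temperature are time-averaged over the final
#' `tail_ns` and attached to the result (attributes `pre_mean_y` and
#' `temperature`); a warning is raised if the temperature misses the target
#' by more than 10%.
#'
#' @param state a [chain_state()] (typically from [initial_state()]).
#' @param params a [pbd_params()].
#' @param cfg an [integrator_config()].
#' @param duration_ns thermalisation length (ns); 0 returns the input.
#' @param tail_ns averaging window for the diagnostics (ns).
#' @param target_temperature expected kinetic temperature (K).
#' @return The thermalised `chain_state` with attributes `pre_mean_y` (A),
#'   `temperature` (K) and `drift`.
#' @export
thermalise <- function(state, params, cfg = integrator_config(),
                       duration_ns = 10, tail_ns = min(1, duration_ns),
                       target_temperature = 310) {
  if (duration_ns == 0) return(state)
  res <- evolve(state, params, cfg, duration_ns,
                record_times_ps = c(0, duration_ns * 1e3),
                window = 1L, accumulate_tail_ns = tail_ns)
  out <- res$state
  temp <- kinetic_temperature(res$record, n_sites = state$n_sites)
  if (is.finite(temp) && abs(temp - target_temperature) >
        0.1 * target_temperature) {
    warning(sprintf("kinetic temperature %.1f K is >10%% from target %.0f K",
                    temp, target_temperature))
  }
  attr(out, "pre_mean_y") <- res$record$tail_mean_y
  attr(out, "temperature") <- temp
  attr(out, "drift") <- res$record$drift
  out
}

#' Insert a Gaussian bubble at fixed total energy
#'
#' Replaces the bubble-region displacements with [bubble_profile()] and
#' rescales all remaining displacements by a common factor lambda, found by
#' bisection on `lambda -> H'(lambda)`, so that the post-insertion energy
#' matches the pre-insertion energy to within `tol` (default 1e-10 eV).
#' Momenta are untouched, so the kinetic temperature is unchanged.
#'
#' @param state a thermalised [chain_state()].
#' @param spec a [bubble_spec()].
#' @param params a [pbd_params()].
#' @param tol energy-matching tolerance (eV).
#' @param max_iter bisection iteration cap.
#' @return The perturbed `chain_state`, with attributes `lambda` and
#'   `energy_error` (eV).
#' @export
insert_bubble <- function(state, spec, params, tol = 1e-10, max_iter = 200) {
  stopifnot(spec$n_sites == state$n_sites)
  H0 <- total_energy(state, params)
  idx <- spec$sites
  prof <- bubble_profile(spec)
  y_out <- state$y[-idx]

  energy_at <- function(lambda) {
    y <- state$y
    y[idx] <- prof
    y[-idx] <- lambda * y_out
    pbd_total_energy_cpp(y, state$p, unclass(params))
  }
  f <- function(lambda) energy_at(lambda) - H0

  lo <- 0; hi <- 1
  flo <- f(lo); fhi <- f(hi)
  if (abs(fhi) <= tol) {
    lambda <- 1
  } else if (abs(flo) <= tol) {
    lambda <- 0
  } else {
    while (flo * fhi > 0 && hi < 8) {
      hi <- hi * 2
      fhi <- f(hi)
    }
    if (flo * fhi > 0) {
      rlang::abort(sprintf(
        paste("bubble insertion infeasible: no rescaling in [0, 8] restores",
              "H; energy shortfall %.4g eV (bubble potential energy exceeds",
              "removable displacement energy)"),
        min(abs(flo), abs(fhi))))
    }
    for (i in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) <= tol || (hi - lo) < 1e-16) break
      if (flo * fm <= 0) {
        hi <- mid; fhi <- fm
      } else {
        lo <- mid; flo <- fm
      }
    }
    lambda <- mid
  }

  y <- state$y
  y[idx] <- prof
  y[-idx] <- lambda * y_out
  out <- chain_state(y, state$p)
  attr(out, "lambda") <- lambda
  attr(out, "energy_error") <- abs(total_energy(out, params) - H0)
  if (attr(out, "energy_error") > tol) {
    warning(sprintf("bubble insertion energy error %.3g eV exceeds tol %.3g",
                    attr(out, "energy_error"), tol))
  }
  out
}

#' Run one bubble-relaxation realisation
#'
#' The full single-run protocol: microcanonical initialisation at the
#' parameter set's energy per site, thermalisation, recording of the
#' pre-insertion chain-mean displacement, Gaussian bubble insertion at fixed
#' total energy, then evolution for `post_ns` with log-time recording of the
#' bubble window (displacements and local energies) and of the total energy.
#' Time t = 0 of the returned record is the insertion instant.
#'
#' @param params a [pbd_params()].
#' @param cfg an [integrator_config()].
#' @param spec a [bubble_spec()].
#' @param seed integer seed identifying the realisation.
#' @param post_ns post-insertion run length (ns).
#' @param thermalisation_ns thermalisation length (ns, default 10).
#' @param record_times_ps recording grid (ps; default [log_time_grid()]).
#' @param thermalised_state optionally, a pre-thermalised [chain_state()]
#'   carrying a `pre_mean_y` attribute (as produced by [thermalise()]); the
#'   initialisation and thermalisation stages are then skipped, which lets an
#'   ensemble of thermalised states be reused across bubble specs.
#' @return An object of class `realisation_result`: fields `seed`, `record`
#'   (window trajectory), `y0_window`, `e0_window`, `pre_insertion_mean_y`,
#'   `lambda`, `spec`, and `energy_per_site`.
#' @export
run_realisation <- function(params, cfg, spec, seed, post_ns,
                            thermalisation_ns = 10, record_times_ps = NULL,
                            thermalised_state = NULL) {
  th <- thermalised_state
  if (is.null(th)) {
    st <- initial_state(spec$n_sites, params$energy_per_site, seed, params)
    th <- thermalise(st, params, cfg, duration_ns = thermalisation_ns)
  }
  pre_mean_y <- attr(th, "pre_mean_y")
  pert <- insert_bubble(th, spec, params)
  res <- evolve(pert, params, cfg, post_ns,
                record_times_ps = record_times_ps, window = spec$sites)
  rec <- res$record
  structure(list(seed = seed,
                 record = rec,
                 y0_window = rec$Y[1, ],
                 e0_window = rec$E[1, ],
                 pre_insertion_mean_y = pre_mean_y,
                 lambda = attr(pert, "lambda"),
                 spec = spec,
                 energy_per_site = params$energy_per_site),
            class = "realisation_result")
}

#' @export
print.realisation_result <- function(x, ...) {
  cat(sprintf("<realisation_result> seed=%d, w=%d, h=%g A, %d recorded instants\n",
              x$seed, x$spec$w, x$spec$h, length(x$record$times_ps)))
  invisible(x)
}
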