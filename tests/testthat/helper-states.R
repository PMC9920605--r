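# Shared helpers: random chain states and small reference evaluations in
# plain R, independent of the compiled kernels.

random_state <- function(n, seed, y_scale = 0.5, p_scale = 3) {
  set.seed(seed)
  chain_state(stats::rnorm(n, sd = y_scale), stats::rnorm(n, sd = p_scale))
}

# Plain-R reference Hamiltonian (periodic), the oracle for the C++ kernels.
reference_energy <- function(state, params) {
  y <- state$y
  p <- state$p
  n <- length(y)
  yprev <- c(y[n], y[-n])
  sum(p^2 / (2 * params$mass)) +
    sum(params$D * (exp(-params$a * y) - 1)^2) +
    sum(0.5 * params$K * (1 + params$rho * exp(-params$b * (y + yprev))) *
          (y - yprev)^2)
}

# Central finite-difference gradient of the reference energy.
reference_forces <- function(state, params, step = 1e-6) {
  vapply(seq_along(state$y), function(i) {
    yp <- state$y; yp[i] <- yp[i] + step
    ym <- state$y; ym[i] <- ym[i] - step
    -(reference_energy(chain_state(yp, state$p), params) -
        reference_energy(chain_state(ym, state$p), params)) / (2 * step)
  }, numeric(1))
}
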