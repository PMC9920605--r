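at <- pbd_params("AT")

test_that("the rest state is a fixed point of the integrator", {
  st <- chain_state(rep(0, 10), rep(0, 10))
  st2 <- symplectic_step(st, at, dt_fs = 10)
  expect_equal(st2$y, rep(0, 10))
  expect_equal(st2$p, rep(0, 10))
})

test_that("small-amplitude uniform mode oscillates at the Morse harmonic frequency", {
  # q = 0 phonon: omega = a sqrt(2 D / m), period ~0.83 ps for AT at 300 amu
  fx <- phonon_fixture(at, q = 0, amplitude = 0.002, n_sites = 8)
  expect_equal(fx$omega, at$a * sqrt(2 * at$D / at$mass), tolerance = 1e-12)
  expect_equal(fx$period_ps, 0.834, tolerance = 1e-3)
  dt <- 1
  res <- evolve(fx$state, at, integrator_config(dt_fs = dt), duration_ns = 5e-3,
                record_times_ps = seq(0, 5, by = dt * 1e-3), window = 1L)
  u <- res$record$Y[, 1]
  tt <- res$record$times_ps
  # zero-crossing frequency estimate (linear interpolation, many periods)
  sgn <- sign(u)
  up <- which(sgn[-1] > 0 & sgn[-length(sgn)] <= 0)
  tc <- tt[up] - u[up] * (tt[up + 1] - tt[up]) / (u[up + 1] - u[up])
  omega_meas <- 2 * pi * (length(tc) - 1) / (tc[length(tc)] - tc[1])
  omega_pred <- fx$freq_per_ps
  expect_lt(abs(omega_meas - omega_pred) / omega_pred, 1e-3)
})

test_that("phonon frequencies match the dispersion relation at q = 0, pi/2, pi", {
  for (par in list(at, pbd_params("GC"))) {
    for (q in c(0, pi / 2, pi)) {
      fx <- phonon_fixture(par, q = q, amplitude = 0.002, n_sites = 16)
      dt <- 0.5
      res <- evolve(fx$state, par, integrator_config(dt_fs = dt),
                    duration_ns = 4e-3,
                    record_times_ps = seq(0, 4, by = dt * 1e-3),
                    window = seq_len(16))
      # project onto the cos(q n) mode to isolate the branch
      mode <- cos(q * seq_len(16))
      u <- as.vector(res$record$Y %*% mode)
      tt <- res$record$times_ps
      sgn <- sign(u)
      up <- which(sgn[-1] > 0 & sgn[-length(sgn)] <= 0)
      tc <- tt[up] - u[up] * (tt[up + 1] - tt[up]) / (u[up + 1] - u[up])
      omega_meas <- 2 * pi * (length(tc) - 1) / (tc[length(tc)] - tc[1])
      expect_lt(abs(omega_meas - fx$freq_per_ps) / fx$freq_per_ps, 1e-3,
                label = sprintf("|rel freq error| (%s, q=%.2f)",
                                par$sequence, q))
    }
  }
})

test_that("time evolution is reversible under momentum reversal", {
  st <- random_state(50, seed = 5, y_scale = 0.3, p_scale = 4)
  cfg <- integrator_config(dt_fs = 10, drift_tolerance = Inf)
  fwd <- evolve(st, at, cfg, duration_ns = 0.01,
                record_times_ps = c(0, 10), window = 1L)
  back <- evolve(chain_state(fwd$state$y, -fwd$state$p), at, cfg,
                 duration_ns = 0.01, record_times_ps = c(0, 10), window = 1L)
  expect_lt(max(abs(back$state$y - st$y)), 1e-6)
})

test_that("symplectic schemes keep the energy bounded where RK4 drifts", {
  st <- initial_state(32, 0.043, seed = 2, params = at)
  drift <- function(scheme, dur) {
    cfg <- integrator_config(dt_fs = 10, scheme = scheme,
                             drift_tolerance = Inf)
    relative_energy_drift(
      evolve(st, at, cfg, duration_ns = dur,
             record_times_ps = seq(0, dur * 1e3, length.out = 21),
             window = 1L)$record)
  }
  d_srkn <- vapply(c(0.1, 1), function(d) drift("srkn6b", d), numeric(1))
  d_verlet <- vapply(c(0.1, 1), function(d) drift("verlet", d), numeric(1))
  d_rk4 <- vapply(c(0.1, 1), function(d) drift("rk4", d), numeric(1))
  expect_lt(d_srkn[2], 1e-7)
  # velocity Verlet: symplectic but lower order — larger yet bounded error
  expect_gt(d_verlet[1], d_srkn[1])
  expect_lt(d_verlet[2] / d_verlet[1], 3)   # bounded, no secular growth
  expect_lt(d_srkn[2] / d_srkn[1], 3)
  # the non-symplectic control accumulates error roughly linearly in time
  expect_gt(d_rk4[2] / d_rk4[1], 5)
})

test_that("energy drift shows 4th-order scaling in the timestep", {
  st <- initial_state(32, 0.043, seed = 8, params = at)
  d <- vapply(c(5, 10), function(dt) {
    cfg <- integrator_config(dt_fs = dt, drift_tolerance = Inf)
    relative_energy_drift(
      evolve(st, at, cfg, duration_ns = 0.1,
             record_times_ps = seq(0, 100, by = 20), window = 1L)$record)
  }, numeric(1))
  expect_gt(d[2] / d[1], 2^3)  # at least cubic gain when halving dt
})

test_that("centre-of-mass momentum is not conserved (on-site potential)", {
  st <- random_state(40, seed = 11, y_scale = 0.4, p_scale = 3)
  res <- evolve(st, at, integrator_config(dt_fs = 10, drift_tolerance = Inf),
                duration_ns = 0.05,
                record_times_ps = c(0, 50), window = 1L)
  expect_gt(abs(sum(res$state$p) - sum(st$p)), 1e-8)
})

test_that("kinetic temperature follows its definition", {
  expect_equal(kinetic_temperature(chain_state(rep(0, 10), rep(0, 10)),
                                   params = at), 0)
  # construct momenta with total KE = N kB 310 / 2 exactly
  N <- 20
  ke <- N * 8.617333262e-5 * 310 / 2
  p <- rep(sqrt(2 * at$mass * ke / N), N)
  expect_equal(kinetic_temperature(chain_state(rep(0, N), p), params = at),
               310, tolerance = 1e-12)
  # numeric method: mean KE in, T out
  expect_equal(kinetic_temperature(ke, n_sites = N), 310, tolerance = 1e-12)
  expect_error(kinetic_temperature(numeric(0), n_sites = N))
})

test_that("relative energy drift is the max deviation from H(0)", {
  rec <- list(H = c(1, 1, 1))
  class(rec) <- "trajectory_record"
  expect_identical(relative_energy_drift(rec), 0)
  rec$H <- c(1.0, 1.0 + 1e-8, 1.0 - 2e-9)
  expect_equal(relative_energy_drift(rec), 1e-8)
  rec$H <- c(0, 1)
  expect_error(relative_energy_drift(rec), "undefined")
})

test_that("evolve handles zero duration and records requested instants", {
  st <- random_state(12, seed = 3)
  out <- evolve(st, at, integrator_config(), duration_ns = 0)
  expect_identical(out$state$y, st$y)
  expect_identical(length(out$record$times_ps), 0L)
  res <- evolve(st, at, integrator_config(dt_fs = 10, drift_tolerance = Inf),
                duration_ns = 0.001,
                record_times_ps = c(0, 0.5, 1), window = c(2L, 5L))
  expect_equal(res$record$times_ps, c(0, 0.5, 1))
  expect_equal(dim(res$record$Y), c(3L, 2L))
  expect_equal(res$record$Y[1, ], st$y[c(2, 5)])
  # log grid starts at 0 and is strictly increasing
  g <- log_time_grid(100)
  expect_identical(g[1], 0)
  expect_true(all(diff(g) > 0))
})

test_that("a diverging trajectory aborts with a diagnostic", {
  st <- chain_state(rep(0, 6), rep(-1e6, 6))  # slams into the Morse wall
  expect_error(
    evolve(st, at, integrator_config(dt_fs = 1e5, drift_tolerance = Inf),
           duration_ns = 1, record_times_ps = c(0, 1000), window = 1L),
    "non-finite|timestep")
})
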