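test_that("noiseless stretched-exponential curves are recovered exactly", {
  fx <- synth_kww_ensemble(A = 0.002, tau_ns = 1.0, beta = 0.8,
                           chi = 0.00185, n_runs = 3, noise_scale = 0,
                           seed = 1)
  fit <- fit_stretched_exponential(fx, t_start_ns = 1e-5)
  expect_equal(fit$A, 0.002, tolerance = 1e-6)
  expect_equal(fit$tau_ns, 1.0, tolerance = 1e-6)
  expect_equal(fit$beta, 0.8, tolerance = 1e-6)
  expect_equal(fit$chi, 0.00185)  # fixed, not fitted
  expect_equal(fit$tau_av_ns, gamma(1 / 0.8) / 0.8 * 1.0, tolerance = 1e-6)
})

test_that("a pure exponential is identified as beta = 1", {
  fx <- synth_kww_ensemble(A = 1, tau_ns = 0.5, beta = 1, chi = 0.2,
                           n_runs = 50, noise_scale = 0.005, seed = 3)
  fit <- fit_stretched_exponential(fx, t_start_ns = 1e-5)
  expect_lt(abs(fit$beta - 1), 0.01)
})

test_that("tau_average follows Gamma(1/beta)/beta * tau", {
  expect_equal(tau_average(1, 1), 1)            # Gamma(1) = 1
  expect_equal(tau_average(1, 0.5), 2)          # Gamma(2)/0.5 = 2
  expect_equal(tau_average(1, 2), sqrt(pi) / 2) # Gamma(0.5) = sqrt(pi)
  expect_equal(tau_average(3.5, 0.7), gamma(1 / 0.7) / 0.7 * 3.5)
  expect_error(tau_average(1, -1), "beta")
  # equals the integral of exp(-(t/tau)^beta) over [0, Inf)
  set.seed(5)
  for (k in 1:20) {
    tau <- runif(1, 0.1, 10)
    beta <- runif(1, 0.3, 1.8)
    num <- stats::integrate(function(t) exp(-(t / tau)^beta), 0, Inf,
                            rel.tol = 1e-12)$value
    expect_equal(tau_average(tau, beta), num, tolerance = 1e-8)
  }
  # monotone increasing in tau at fixed beta
  taus <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(tau_average(taus, 0.7)) > 0))
})

test_that("the fit start lands after a constructed oscillatory stage", {
  # damped oscillation riding on a KWW decay, oscillations dead by ~20 ps
  times <- log_time_grid(2e4)  # 20 ns
  t_ns <- times / 1e3
  base <- 0.002 * exp(-(t_ns / 1)^0.8) + 0.00185
  osc <- 5e-4 * exp(-times / 8) * cos(2 * pi * times / 3)
  per_run <- sapply(1:40, function(r) {
    set.seed(r)
    base + osc + rnorm(length(times), sd = 2e-6)
  })
  s <- ensemble_stats(per_run, times, chi = 0.00185)
  ts <- select_fit_start(s)
  expect_gt(ts, 0.01)   # past the oscillations (>10 ps)
  expect_lt(ts, 0.08)   # but not deep into the decay
  # a strictly decreasing series starts at the first grid point
  mono <- ensemble_stats(sapply(1:5, function(i) exp(-t_ns)), times,
                         chi = 0)
  expect_equal(select_fit_start(mono), times[1] / 1e3)
  # pathological: monotonically rising series has no decay tail
  rising <- ensemble_stats(sapply(1:5, function(i) t_ns), times, chi = 0)
  expect_error(select_fit_start(rising), "monotone|longer")
})

test_that("the fit-window end truncates converged noisy tails", {
  times <- log_time_grid(2e4)
  t_ns <- times / 1e3
  chi <- 0.002
  truth <- 0.002 * exp(-(t_ns / 0.5)^0.8) + chi
  per_run <- sapply(1:30, function(r) {
    set.seed(r); truth + rnorm(length(times), sd = 1e-5)
  })
  s <- ensemble_stats(per_run, times, chi = chi)
  te <- select_fit_end(s, t_start_ns = 0.01)
  # the curve reaches chi a few tau_av past the decay, well before 20 ns
  expect_gt(te, 0.5)
  expect_lt(te, 10)
  # a series that never converges is not truncated
  flat <- ensemble_stats(sapply(1:5, function(i) truth + 0.001), times,
                         chi = chi)
  expect_null(select_fit_end(flat, t_start_ns = 0.01))
  # windowed fit still recovers the generative parameters
  f <- fit_stretched_exponential(s, t_start_ns = 0.01, t_end_ns = te)
  expect_equal(f$tau_ns, 0.5, tolerance = 0.05)
  expect_equal(f$beta, 0.8, tolerance = 0.05)
})

test_that("multi-start fitting escapes the degenerate small-beta ridge", {
  # single-start and multi-start agree on clean data
  fx <- synth_kww_ensemble(0.002, 1, 0.8, 0.0018, n_runs = 40,
                           noise_scale = 1e-4, seed = 5)
  f1 <- fit_stretched_exponential(fx, t_start_ns = 1e-4, multistart = FALSE)
  f2 <- fit_stretched_exponential(fx, t_start_ns = 1e-4)
  expect_equal(f1$tau_ns, f2$tau_ns, tolerance = 1e-6)
  # beta honours a custom range
  f3 <- fit_stretched_exponential(fx, t_start_ns = 1e-4,
                                  beta_range = c(0.75, 0.85))
  expect_gte(f3$beta, 0.75)
  expect_lte(f3$beta, 0.85)
})

test_that("KWW parameter recovery holds across a (A, tau, beta) grid with noise", {
  grid <- expand.grid(A = c(0.001, 0.003), tau = c(0.5, 2), beta = c(0.6, 0.9))
  rel_err <- mapply(function(A, tau, beta) {
    fx <- synth_kww_ensemble(A, tau, beta, chi = A * 0.9, n_runs = 200,
                             noise_scale = 0.05 * A,
                             seed = round(1000 * A * tau * beta))
    fit <- fit_stretched_exponential(fx, t_start_ns = 1e-4)
    c(beta_err = abs(fit$beta - beta),
      tauav_rel = abs(fit$tau_av_ns - tau_average(tau, beta)) /
        tau_average(tau, beta))
  }, grid$A, grid$tau, grid$beta)
  expect_lt(max(rel_err["beta_err", ]), 0.05)
  expect_lt(stats::median(rel_err["tauav_rel", ]), 0.05)
})

test_that("bootstrap uncertainties are reproducible and vanish for identical runs", {
  fx <- synth_kww_ensemble(0.002, 1, 0.8, 0.0018, n_runs = 30,
                           noise_scale = 0, seed = 2)
  fit <- fit_stretched_exponential(fx, t_start_ns = 1e-4)
  b1 <- bootstrap_uncertainty(fx, fit, n_boot = 50, seed = 9)
  expect_lt(b1$se$tau_ns, 1e-8)   # zero scatter between identical runs
  fx2 <- synth_kww_ensemble(0.002, 1, 0.8, 0.0018, n_runs = 40,
                            noise_scale = 1e-4, seed = 4)
  fit2 <- fit_stretched_exponential(fx2, t_start_ns = 1e-4)
  b2a <- bootstrap_uncertainty(fx2, fit2, n_boot = 60, seed = 11)
  b2b <- bootstrap_uncertainty(fx2, fit2, n_boot = 60, seed = 11)
  expect_identical(b2a$se, b2b$se)
  expect_gt(b2a$se$tau_av_ns, 0)
})

test_that("bootstrap spread tracks the generative ensemble scatter", {
  # true sampling std of tau_av: refit many independent ensembles
  A <- 0.002; tau <- 1; beta <- 0.8; chi <- 0.0018
  tav <- vapply(1:40, function(s) {
    fx <- synth_kww_ensemble(A, tau, beta, chi, n_runs = 60,
                             noise_scale = 2e-4, seed = 100 + s)
    fit_stretched_exponential(fx, t_start_ns = 1e-4)$tau_av_ns
  }, numeric(1))
  gen_sd <- stats::sd(tav)
  fx <- synth_kww_ensemble(A, tau, beta, chi, n_runs = 60,
                           noise_scale = 2e-4, seed = 7)
  fit <- fit_stretched_exponential(fx, t_start_ns = 1e-4)
  boot <- bootstrap_uncertainty(fx, fit, n_boot = 200, seed = 1)
  expect_lt(abs(boot$se$tau_av_ns - gen_sd) / gen_sd, 0.5)
})

test_that("amplitude trends recover exact and degenerate lines", {
  h <- c(2.5, 3.5, 4.5, 5.5)
  tf <- amplitude_linear_fit(data.frame(h = h, tau_av = 1 + 0.5 * h),
                             width = 11)
  expect_equal(tf$tau0, 1, tolerance = 1e-10)
  expect_equal(tf$alpha, 0.5, tolerance = 1e-10)
  tf0 <- amplitude_linear_fit(data.frame(h = h, tau_av = rep(2, 4)),
                              width = 11)
  expect_equal(tf0$alpha, 0, tolerance = 1e-12)
  expect_error(amplitude_linear_fit(data.frame(h = c(1, 1, 1),
                                               tau_av = 1:3), width = 9),
               "distinct")
  # weighted fit reduces to unweighted under equal sems
  d <- data.frame(h = h, tau_av = c(1.1, 1.9, 3.2, 3.9),
                  tau_av_sd = rep(0.2, 4))
  tw <- amplitude_linear_fit(d, width = 9)
  tu <- amplitude_linear_fit(d[, 1:2], width = 9)
  expect_equal(tw$alpha, tu$alpha, tolerance = 1e-12)
  expect_equal(tw$tau0, tu$tau0, tolerance = 1e-12)
})

test_that("width trends compose the closed-form relaxation-time map", {
  # synthetic tau_av(w, h) = (0.07 w - 0.6) + 0.24 h, exactly linear
  widths <- c(9, 11, 13, 15, 17, 19)
  trends <- lapply(widths, function(w) {
    h <- seq(2.5, 5.5, by = 1)
    amplitude_linear_fit(
      data.frame(h = h, tau_av = (0.07 * w - 0.6) + 0.24 * h), width = w)
  })
  wt <- width_trend_fit(trends)
  expect_equal(wt$tau0_line$slope, 0.07, tolerance = 1e-8)
  expect_equal(wt$tau0_line$intercept, -0.6, tolerance = 1e-8)
  expect_equal(wt$alpha_line$slope, 0, tolerance = 1e-8)
  expect_equal(wt$alpha_line$intercept, 0.24, tolerance = 1e-8)
  expect_equal(wt$predict(19, 5), (0.07 * 19 - 0.6) + 0.24 * 5)
  expect_error(width_trend_fit(trends[1:2]), "3 distinct")
})

test_that("tidy and glance methods return broom-shaped tibbles", {
  fx <- synth_kww_ensemble(0.002, 1, 0.8, 0.0018, n_runs = 5,
                           noise_scale = 0, seed = 1)
  fit <- fit_stretched_exponential(fx, t_start_ns = 1e-4)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("A", "tau_ns", "beta", "tau_av_ns"))
  gl <- glance(fit)
  expect_equal(gl$tau_av_ns, fit$tau_av_ns)
  tf <- amplitude_linear_fit(
    data.frame(h = c(2, 3, 4), tau_av = c(1, 2, 3)), width = 9)
  expect_equal(tidy(tf)$estimate, c(tf$tau0, tf$alpha))
})

test_that("uncertainties format in compact parenthesis notation", {
  expect_equal(format_uncertainty(0.238, 0.082), "0.24(8)")
  expect_equal(format_uncertainty(-0.61, 0.3), "-0.6(3)")
  expect_equal(format_uncertainty(23.4, 5.2), "23(5)")
  expect_equal(format_uncertainty(118, 70), "120(70)")
  expect_equal(format_uncertainty(0.0703, 0.021), "0.07(2)")
  expect_equal(format_uncertainty(1.5, NA), "1.5")
})
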