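test_that("OU generator is seeded, stationary and exponentially correlated", {
  # determinism and the single-draw initialization case
  expect_identical(generate_unit_ou(1000, dt = 0.05, seed = 7),
                   generate_unit_ou(1000, dt = 0.05, seed = 7))
  expect_length(generate_unit_ou(1, dt = 0.05, tau_corr = 5, seed = 1), 1)
  expect_error(generate_unit_ou(100, dt = -1), "dt")
  expect_error(generate_unit_ou(100, dt = 0.05, tau_corr = 0), "tau_corr")
  expect_warning(generate_unit_ou(10, dt = 3, tau_corr = 5), "under-sampled")

  # stationary moments: 3-standard-error bounds from the effective sample
  # count n*dt/(2*tau) of a 100-s realization
  n <- 2e6; dt <- 0.05; tau <- 5
  eta <- generate_unit_ou(n, dt, tau, seed = 42)
  se_mean <- sqrt(2 * tau / (n * dt))
  se_var <- sqrt(2 * 2 * tau / (n * dt))
  expect_lt(abs(mean(eta)), 3 * se_mean)
  expect_lt(abs(mean(eta^2) - 1), 3 * se_var)

  # correlation time recovered by an exponential fit to the autocorrelation
  tr <- compose_stimulus(eta, i0 = 0, sigma = 1, dt = dt)
  ac <- autocorrelation(tr, max_lag = 60)
  ft <- fit_ac_timeconstant(ac, fit_max_lag = 50)
  expect_lt(abs(ft$tau - tau) / tau, 0.05)
  # and the lag-domain values follow the exp(-|lag|/tau) closed form
  sel <- abs(ac$lags) <= 25
  expect_lt(max(abs(ac$values[sel] - exp(-abs(ac$lags[sel]) / tau))), 0.05)
})

test_that("compose_stimulus propagates moments and degenerate cases", {
  expect_equal(compose_stimulus(rnorm(100), i0 = 50, sigma = 0, dt = 0.05)$values,
               rep(50, 100))
  eta <- generate_unit_ou(1000, 0.05, seed = 3)
  expect_equal(compose_stimulus(eta, i0 = 0, sigma = 1, dt = 0.05)$values, eta)
  big <- ou_current(2e6, 0.05, 5, i0 = 100, sigma = 20, seed = 9)
  expect_lt(abs(mean(big$values) - 100), 3 * 20 * sqrt(2 * 5 / 1e5))
  expect_lt(abs(sd(big$values) - 20) / 20, 0.02)
  expect_error(compose_stimulus(eta, i0 = 0, sigma = -1, dt = 0.05), "sigma")
})

test_that("autocorrelation matches a brute-force oracle on toy inputs", {
  # constant trace: no fluctuation, all lags zero
  ac0 <- autocorrelation(current_trace(rep(5, 100), dt = 1), max_lag = 10)
  expect_equal(ac0$values, rep(0, 21))
  # toy trace, biased normalization, computed by hand:
  # lag 0 = 4/4 = 1; lag 1 = (-1 -1 -1)/4 = -0.75
  ac <- autocorrelation(current_trace(c(1, -1, 1, -1), dt = 1), max_lag = 2)
  i0 <- (length(ac$values) + 1) / 2
  expect_equal(ac$values[i0], 1)
  expect_equal(ac$values[i0 + 1], -0.75)
  expect_equal(ac$values[i0 - 1], -0.75)   # symmetric by construction
  expect_equal(ac$values, rev(ac$values))
  expect_error(autocorrelation(current_trace(1:10, dt = 1), max_lag = 10),
               "max_lag")
})

test_that("bisection calibrators invert monotone responses within tolerance", {
  # synthetic rate law r(i0) = 0.1 * (i0 - 100): target 5 -> i0 = 150
  r <- function(i0) pmax(0, 0.1 * (i0 - 100))
  cal <- calibrate_dc(r, 5, bounds = c(100, 200), tol = 0.01)
  expect_true(cal$converged)
  expect_lt(abs(cal$value - 150), 0.2)
  # iteration bound on a monotone evaluator
  expect_lte(cal$n_iter, ceiling(log2((200 - 100) / (0.01 / 0.1))))
  # target below the rate at the lower bound: bracketing error
  expect_error(calibrate_dc(r, 5, bounds = c(160, 200), tol = 0.01),
               "bracket")
  # sigma calibration: SD(sigma) = sigma/10, target 4 -> sigma = 40
  sig <- calibrate_sigma(function(s) s / 10, 4, bounds = c(1, 100), tol = 0.001)
  expect_lt(abs(sig$value - 40), 0.1)
  expect_error(calibrate_sigma(function(s) s / 10, 0, bounds = c(10, 100)),
               "bracket")
})

test_that("DC calibration closes the loop on a LIF simulator", {
  p <- if_params()
  dt <- 0.05
  etas <- lapply(1:2, function(r) generate_unit_ou(2e5, dt, 5, seed = 100 + r))
  eval_rate <- function(i0) {
    n <- vapply(etas, function(eta) {
      stim <- compose_stimulus(eta, i0 = i0, sigma = 65, dt = dt)
      length(simulate_if(p, stim)$spikes$times)
    }, numeric(1))
    sum(n) / (2 * 2e5 * dt / 1000)
  }
  cal <- calibrate_dc(eval_rate, 5, bounds = c(0, 1500), tol = 0.2)
  expect_true(cal$converged)
  # closed-loop check: re-simulation at the calibrated DC hits the target
  expect_lte(abs(eval_rate(cal$value) - 5), 0.2)
})

test_that("current traces round-trip through CSV", {
  tr <- ou_current(200, 0.05, 5, i0 = 10, sigma = 2, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_current_csv(tr, path)
  back <- read_current_csv(path)
  expect_equal(back$values, tr$values, tolerance = 1e-8)
  expect_equal(back$dt, tr$dt, tolerance = 1e-8)
  unlink(path)
})
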