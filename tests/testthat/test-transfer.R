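test_that("STA of a single spike is the reversed current segment", {
  set.seed(1)
  cur <- current_trace(rnorm(1201), dt = 1)
  trial <- list(list(current = cur, spikes = spike_train(600, 1201)))
  sta <- compute_sta(trial, T = 500)
  # sta(lag) = i(t_k - lag): ascending lags read the current backwards
  expect_equal(sta$values, rev(cur$values[101:1101]))
  expect_equal(sta$n_spikes_used, 1L)
})

test_that("STA equals the naive per-spike loop on random instances", {
  set.seed(7)
  for (r in 1:30) {
    n <- sample(150:400, 1)
    cur <- current_trace(rnorm(n), dt = 1)
    T <- sample(10:40, 1)
    times <- sort(sample(seq(T + 1, n - 2 - T), sample(1:50, 1)))
    sp <- spike_train(times, n)
    sta <- compute_sta(list(list(current = cur, spikes = sp)), T = T)
    oracle <- sta_naive(cur$values, sp$times, 1, T)
    expect_equal(sta$values, oracle, tolerance = 1e-12)
  }
  # two-spike case against an explicit mean of two windows
  cur <- current_trace(rnorm(400), dt = 1)
  sp <- spike_train(c(150, 250), 400)
  sta <- compute_sta(list(list(current = cur, spikes = sp)), T = 100)
  byhand <- (rev(cur$values[51:251]) + rev(cur$values[151:351])) / 2
  expect_equal(sta$values, byhand)
})

test_that("STA of a current-independent Poisson train is flat at i0", {
  dt <- 0.05
  cur <- ou_current(round(60e3 / dt), dt, 5, i0 = 100, sigma = 30, seed = 3)
  sp <- poisson_train(60e3, 10, seed = 4)
  sta <- compute_sta(list(list(current = cur, spikes = sp)), T = 500)
  se <- 30 / sqrt(sta$n_spikes_used)    # per-lag sampling error scale
  expect_lt(abs(mean(sta$values) - 100), 3 * se)
  expect_lt(max(abs(sta$values - mean(sta$values))), 6 * se)
})

test_that("transfer of identical numerator and denominator is unity", {
  tr <- ou_current(round(30e3 / 0.05), 0.05, 5, i0 = 50, sigma = 20, seed = 9)
  iac <- autocorrelation(tr, max_lag = 200)
  sta <- as_sta_result(iac$lags, iac$values, iac$dt)
  tf <- estimate_transfer(sta, iac, bins_per_decade = NULL)
  expect_lt(max(abs(tf$magnitude - 1), na.rm = TRUE), 1e-8)
  expect_lt(max(abs(tf$phase), na.rm = TRUE), 1e-8)
})

test_that("a pure delay obeys the Fourier shift theorem", {
  dt <- 0.05
  tr <- ou_current(round(30e3 / dt), dt, 5, i0 = 0, sigma = 20, seed = 10)
  iac <- autocorrelation(tr, max_lag = 200)
  shift <- round(5 / dt)                        # 5-ms delay
  delayed <- c(rep(0, shift), head(iac$values, -shift))
  tf <- estimate_transfer(as_sta_result(iac$lags, delayed, dt), iac,
                          bins_per_decade = NULL)
  sel <- tf$freqs >= 1 & tf$freqs <= 50
  expect_lt(max(abs(tf$magnitude[sel] - 1)), 0.02)
  # phase slope -2*pi*delay: fit in (rad per Hz), delay in seconds
  delay_s <- -coef(lm(tf$phase[sel] ~ tf$freqs[sel]))[[2]] / (2 * pi)
  expect_equal(delay_s, 0.005, tolerance = 0.01)
})

test_that("cut-off extraction matches the single-pole closed form", {
  f <- 10^seq(log10(0.5), 3, length.out = 2500)
  mag1 <- function(f) 1 / sqrt(1 + (f / 100)^2)
  tf <- transfer_function(f, mag1(f))
  co <- cutoff_frequency(tf)
  # independent oracle: solve |H|(f) = 0.7 |H|(1) directly
  f_oracle <- stats::uniroot(function(x) mag1(x) - 0.7 * mag1(1),
                             c(50, 200), tol = 1e-10)$root
  expect_true(co$defined)
  expect_equal(f_oracle, 102.03, tolerance = 1e-3)
  expect_lt(abs(co$f_cut - f_oracle), 0.4)      # one interpolation step
  # scale invariance
  co2 <- cutoff_frequency(transfer_function(f, 37.5 * mag1(f)))
  expect_equal(co2$f_cut, co$f_cut)
  # flat magnitude: undefined and flagged
  flat <- cutoff_frequency(transfer_function(f, rep(2, length(f))))
  expect_false(flat$defined)
  expect_match(flat$reason, "no crossing")
})

test_that("power-law fit is exact on exact power laws", {
  f <- 10^seq(0, 3, length.out = 400)
  pl <- powerlaw_fit(transfer_function(f, 3 * f^-0.5), f_cut = 10)
  expect_equal(pl$alpha, 0.5, tolerance = 1e-10)
  expect_equal(pl$b, 3, tolerance = 1e-10)
  pl1 <- powerlaw_fit(transfer_function(f, f^-1), f_cut = 5)
  expect_equal(pl1$alpha, 1, tolerance = 1e-10)
  # the band stops at 20% of the cut-off magnitude
  expect_lt(pl1$fit_range[2], 5 * 5.2)
  expect_error(powerlaw_fit(transfer_function(f[1:6], f[1:6]^-1), f_cut = 900),
               "bins")
})

test_that("ISI coefficient of variation uses the population SD", {
  expect_equal(isi_cv(spike_train(seq(10, 1000, by = 10), 1001)), 0)
  expect_equal(isi_cv(c(40, 60)), 0.2)
  cv <- isi_cv(poisson_train(2e5, 10, seed = 12))   # exponential ISIs
  expect_equal(cv, 1, tolerance = 0.08)
})

test_that("f_cut and alpha are invariant under current rescaling", {
  dt <- 0.05
  trials <- make_if_trials(if_params(), 3, 60e3, i0 = 88, sigma = 65, seed = 60)
  trials <- lapply(trials, function(tr) tr[c("current", "spikes")])
  sta <- compute_sta(trials, T = 500)
  iac <- autocorrelation(lapply(trials, `[[`, "current"), max_lag = 500)
  tf <- estimate_transfer(sta, iac)
  co <- cutoff_frequency(tf)
  # multiply the current by a constant: sta x c, PSD x c^2, |H| x 1/c
  c0 <- 3.7
  scaled <- lapply(trials, function(tr) {
    tr$current$values <- tr$current$values * c0
    tr
  })
  sta2 <- compute_sta(scaled, T = 500)
  iac2 <- autocorrelation(lapply(scaled, `[[`, "current"), max_lag = 500)
  tf2 <- estimate_transfer(sta2, iac2)
  co2 <- cutoff_frequency(tf2)
  expect_equal(co2$f_cut, co$f_cut, tolerance = 1e-6)
  expect_equal(tf2$magnitude * c0, tf$magnitude, tolerance = 1e-6)
  pl <- powerlaw_fit(tf, co$f_cut)
  pl2 <- powerlaw_fit(tf2, co2$f_cut)
  expect_equal(pl2$alpha, pl$alpha, tolerance = 1e-6)
})

test_that("surrogate threshold flags a driven train and validates inputs", {
  trials <- make_if_trials(if_params(), 2, 60e3, i0 = 88, sigma = 65, seed = 80)
  trials <- lapply(trials, function(tr) tr[c("current", "spikes")])
  expect_error(surrogate_threshold(trials, n_surrogates = 1), ">= 2")
  iac <- autocorrelation(lapply(trials, `[[`, "current"), max_lag = 500)
  sta <- compute_sta(trials, T = 500)
  tf <- estimate_transfer(sta, iac)
  thr <- surrogate_threshold(trials, T = 500, n_surrogates = 100, seed = 5,
                             iac = iac)
  # reproducible given the seed
  thr2 <- surrogate_threshold(trials, T = 500, n_surrogates = 100, seed = 5,
                              iac = iac)
  expect_identical(thr$threshold, thr2$threshold)
  tf <- set_significance(tf, thr)
  sm <- tf$smoothing
  # a stimulus-driven train is significant over a contiguous low-frequency band
  low <- sm$freqs <= 5
  expect_true(all(sm$values[low] > sm$threshold[low]))
})

test_that("exponential spike initiation steepens the high-frequency decay", {
  # rate-matched (~4.5 spike/s) LIF and EIF driven by the same noise seeds
  run_alpha <- function(params, i0, seed) {
    trials <- make_if_trials(params, 8, 60e3, i0 = i0, sigma = 68, seed = seed)
    trials <- lapply(trials, function(tr) tr[c("current", "spikes")])
    sta <- compute_sta(trials, T = 500)
    iac <- autocorrelation(lapply(trials, `[[`, "current"), max_lag = 500)
    tf <- estimate_transfer(sta, iac)
    thr <- surrogate_threshold(trials, T = 500, n_surrogates = 150, seed = 1,
                               iac = iac)
    tf <- set_significance(tf, thr)
    co <- cutoff_frequency(tf)
    powerlaw_fit(tf, co$f_cut)$alpha
  }
  a_lif <- run_alpha(if_params(), i0 = 85, seed = 300)
  a_eif <- run_alpha(if_params(delta_T = 1.5), i0 = 95, seed = 300)
  expect_gt(a_eif, a_lif)
})
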