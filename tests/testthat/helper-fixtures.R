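# Shared fixtures and independent oracles, built in code at test time.

# homogeneous Poisson spike train (independent of any stimulus)
poisson_train <- function(duration, rate, seed) {
  set.seed(seed)
  ts <- cumsum(stats::rexp(ceiling(3 * rate * duration / 1000), rate / 1000))
  spike_train(ts[ts < duration], duration)
}

# naive per-spike loop STA: the brute-force oracle for compute_sta
sta_naive <- function(current, times, dt, T) {
  m <- round(T / dt)
  acc <- numeric(2 * m + 1)
  cnt <- 0
  for (tk in times) {
    c0 <- round(tk / dt) + 1
    if (c0 - m >= 1 && c0 + m <= length(current)) {
      acc <- acc + current[c0 - (-m:m)]
      cnt <- cnt + 1
    }
  }
  acc / cnt
}

# textbook Pearson correlation + two-sided t-test p-value
pearson_manual <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p_value = 2 * stats::pt(-abs(tt), n - 2))
}

# textbook Kruskal-Wallis H with tie correction
kruskal_manual <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  tie <- table(x)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# wrap a lag-domain curve as an sta_result (for ratio-identity style tests)
as_sta_result <- function(lags, values, dt) {
  structure(list(lags = lags, values = values, dt = dt,
                 n_spikes_used = 1L, n_trials = 1L, T = max(lags)),
            class = "sta_result")
}

# small LIF/EIF trial set for spectral tests: list of (current, spikes)
make_if_trials <- function(params, n_trials, trial_ms, i0, sigma,
                           dt = 0.05, tau_corr = 5, seed = 1) {
  lapply(seq_len(n_trials), function(j) {
    stim <- ou_current(round(trial_ms / dt), dt, tau_corr, i0 = i0,
                       sigma = sigma, seed = seed + j)
    out <- simulate_if(params, stim)
    list(current = stim, spikes = out$spikes, voltage = out$voltage)
  })
}

etype_labels <- c("cAC", "cNAC", "bNAC", "cSTUT", "cIR")
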