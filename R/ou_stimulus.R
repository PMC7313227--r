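#' Generate a unit-variance Ornstein-Uhlenbeck process
#'
#' Stationary, exact-update realization of the zero-mean, unit-variance OU
#' process with exponential autocorrelation `exp(-|lag|/tau_corr)`.  The
#' recursion is
#' \deqn{\eta_{k+1} = \eta_k e^{-dt/\tau} + \sqrt{1 - e^{-2 dt/\tau}}\,\xi_k}
#' with \eqn{\xi_k} i.i.d. standard normal and \eqn{\eta_0} drawn standard
#' normal, so the process starts in its stationary distribution and needs no
#' burn-in.  Identical `seed` gives bit-identical output.
#'
#' @param n number of samples (>= 1).
#' @param dt sample interval (ms).  A warning is issued when `dt >
#'   tau_corr/5`, where the discrete autocorrelation departs visibly from the
#'   continuous-time target.
#' @param tau_corr correlation time (ms); default 5 ms.
#' @param seed integer RNG seed, or `NULL` to draw from the current stream.
#' @return numeric vector of length `n`.
#' @examples
#' eta <- generate_unit_ou(1e5, dt = 0.05, tau_corr = 5, seed = 1)
#' c(mean(eta), stats::var(eta))
#' @export
generate_unit_ou <- function(n, dt, tau_corr = 5, seed = NULL) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(tau_corr, "tau_corr", positive = TRUE)
  stopifnot_scalar(n, "n", positive = TRUE)
  n <- as.integer(n)
  if (dt > tau_corr / 5)
    warning("dt > tau_corr/5: OU process is under-sampled")
  a <- exp(-dt / tau_corr)
  b <- sqrt(1 - a * a)
  with_seed(seed, {
    eta0 <- stats::rnorm(1)
    if (n == 1L) {
      eta0
    } else {
      xi <- stats::rnorm(n - 1L)
      rest <- stats::filter(b * xi, a, method = "recursive", init = eta0)
      c(eta0, as.numeric(rest))
    }
  })
}

#' Compose an injected-current stimulus i(t) = i0 + sigma * eta(t)
#'
#' @param eta unit-variance noise realization (e.g. from
#'   [generate_unit_ou()]).
#' @param i0 DC offset (pA).
#' @param sigma fluctuation standard deviation (pA), >= 0.
#' @param dt sample interval (ms).
#' @param tau_corr optional metadata: correlation time of `eta`.
#' @return a [current_trace()].
#' @export
compose_stimulus <- function(eta, i0, sigma, dt, tau_corr = NA_real_) {
  stopifnot_scalar(i0, "i0")
  stopifnot_scalar(sigma, "sigma")
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (!all(is.finite(eta))) stop("`eta` must be finite")
  current_trace(i0 + sigma * as.numeric(eta), dt = dt, i0 = i0, sigma = sigma,
                tau_corr = tau_corr)
}

#' One-call OU current stimulus
#'
#' Convenience wrapper: [generate_unit_ou()] followed by
#' [compose_stimulus()].
#'
#' @inheritParams generate_unit_ou
#' @inheritParams compose_stimulus
#' @return a [current_trace()].
#' @export
ou_current <- function(n, dt, tau_corr = 5, i0 = 0, sigma = 1, seed = NULL) {
  eta <- generate_unit_ou(n, dt, tau_corr, seed = seed)
  compose_stimulus(eta, i0 = i0, sigma = sigma, dt = dt, tau_corr = tau_corr)
}

#' Sample autocorrelation of a current trace
#'
#' Biased (1/n) estimator of the autocovariance
#' `<(i(t) - mean)(i(t - lag) - mean)>` on a symmetric lag grid
#' `[-max_lag, max_lag]`, computed by FFT.  The mean is subtracted first;
#' with several trials the per-trial autocorrelations are averaged.  The 1/n
#' normalization keeps the implied power spectral density non-negative
#' definite.
#'
#' @param trace a [current_trace()] or a list of them (same `dt` and length
#'   not required across trials, but same `dt` is).
#' @param max_lag maximum lag (ms); must be shorter than each trial.
#' @return An object of class `autocorrelation` with fields `lags` (ms,
#'   symmetric about 0), `values` (pA^2) and `dt`.
#' @export
autocorrelation <- function(trace, max_lag) {
  traces <- if (inherits(trace, "current_trace")) list(trace) else trace
  if (!length(traces) || !all(vapply(traces, inherits, TRUE, "current_trace")))
    stop("`trace` must be a current_trace or a list of them")
  dt <- traces[[1]]$dt
  if (!all(vapply(traces, function(x) isTRUE(all.equal(x$dt, dt)), TRUE)))
    stop("all trials must share the same dt")
  stopifnot_scalar(max_lag, "max_lag", positive = TRUE)
  m <- as.integer(round(max_lag / dt))
  acc <- NULL
  for (tr in traces) {
    n <- length(tr$values)
    if (max_lag >= n * dt) stop("`max_lag` must be smaller than the trace duration")
    x <- tr$values - mean(tr$values)
    nfft <- stats::nextn(n + m + 1L, c(2L, 3L, 5L))
    X <- stats::fft(c(x, numeric(nfft - n)))
    s <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nfft
    pos <- s[seq_len(m + 1L)] / n   # biased normalization
    acc <- if (is.null(acc)) pos else acc + pos
  }
  pos <- acc / length(traces)
  structure(list(lags = seq(-m, m) * dt,
                 values = c(rev(pos[-1]), pos),
                 dt = dt),
            class = "autocorrelation")
}

#' @export
print.autocorrelation <- function(x, ...) {
  cat(sprintf("<autocorrelation> lags in [%g, %g] ms (dt = %g), var = %.3g pA^2\n",
              min(x$lags), max(x$lags), x$dt, x$values[(length(x$values) + 1) / 2]))
  invisible(x)
}

#' Fit an exponential decay to an autocorrelation and return its time constant
#'
#' Least-squares fit of `A * exp(-lag/tau)` to the non-negative-lag branch of
#' an autocorrelation over `lags <= fit_max_lag`, used to verify the
#' correlation time of a generated stimulus.
#'
#' @param ac an [autocorrelation()] result.
#' @param fit_max_lag largest lag (ms) entering the fit; default 50 ms.
#' @return list with `tau` (ms), `A` (pA^2) and the `nls` fit object.
#' @export
fit_ac_timeconstant <- function(ac, fit_max_lag = 50) {
  stopifnot(inherits(ac, "autocorrelation"))
  sel <- ac$lags >= 0 & ac$lags <= fit_max_lag
  lag <- ac$lags[sel]
  y <- ac$values[sel]
  A0 <- max(y[1], .Machine$double.eps)
  # log-linear start from the clearly positive part of the decay
  pos <- y > 0.05 * A0
  tau0 <- tryCatch(-1 / coef(lm(log(y[pos]) ~ lag[pos]))[[2]], error = function(e) NA)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(lag[which(y < A0 / exp(1))[1]], 1)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-lag / tau),
                           start = list(A = A0, tau = tau0),
                           lower = c(A = 0, tau = 1e-3),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- coef(fit)
  list(tau = p[["tau"]], A = p[["A"]], fit = fit)
}
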