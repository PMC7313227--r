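#' Spike-triggered average of the injected current
#'
#' Mean, pooled over all spikes of all trials, of the current segment
#' `i(t_k - t)` for lags `t` in `[-T, T]`.  Positive lag means current
#' *preceding* the spike.  Spikes whose lag window exceeds the trial
#' boundaries are excluded.
#'
#' @param trials list of `list(current = <current_trace>, spikes =
#'   <spike_train>)`; each trial must last at least `2*T`.
#' @param T lag half-window (ms); default 500.
#' @return object of class `sta_result`: `lags` (ms, symmetric about 0,
#'   positive = preceding), `values` (pA), `dt`, `n_spikes_used`,
#'   `n_trials`, `T`.
#' @export
compute_sta <- function(trials, T = 500) {
  if (!length(trials)) stop("`trials` must be a non-empty list")
  dt <- trials[[1]]$current$dt
  m <- as.integer(round(T / dt))
  total <- numeric(2L * m + 1L)
  used <- 0L
  for (tr in trials) {
    cur <- tr$current; sp <- tr$spikes
    stopifnot(inherits(cur, "current_trace"), inherits(sp, "spike_train"))
    if (!isTRUE(all.equal(cur$dt, dt))) stop("all trials must share the same dt")
    n <- length(cur$values)
    if (n * dt < 2 * T) stop("each trial must be at least 2*T long")
    idx <- as.integer(round(sp$times / dt)) + 1L
    idx <- idx[idx - m >= 1L & idx + m <= n]
    if (length(idx)) {
      total <- total + sta_sums_cpp(cur$values, idx, m)
      used <- used + length(idx)
    }
  }
  if (used == 0L) stop("no usable spikes (all windows truncated)")
  structure(list(lags = seq(-m, m) * dt, values = total / used, dt = dt,
                 n_spikes_used = used, n_trials = length(trials), T = T),
            class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf("<sta_result> T = %g ms, dt = %g ms, %d spikes over %d trial(s)\n",
              x$T, x$dt, x$n_spikes_used, x$n_trials))
  invisible(x)
}

# reorder a symmetric lag-domain vector (lag -T..T) so lag 0 comes first
lag_wrap <- function(v) {
  n <- length(v)
  m <- (n - 1L) %/% 2L
  c(v[(m + 1L):n], v[seq_len(m)])
}

# positive-frequency grid (Hz, excluding 0) and PSD of an autocorrelation;
# bins whose power is below tolerance are masked (NA) rather than divided by.
psd_positive <- function(iac, psd_rel_tol = 1e-12) {
  n <- length(iac$values)
  keep <- seq.int(2L, (n + 1L) %/% 2L)
  P <- Re(stats::fft(lag_wrap(iac$values)))[keep]
  P[P <= max(P) * psd_rel_tol] <- NA_real_
  freqs <- (keep - 1L) / (n * iac$dt * 1e-3)   # cycle/s
  list(freqs = freqs, P = P, keep = keep)
}

# geometric-frequency binning: log-spaced bins, bins_per_decade per decade;
# returns per-bin geometric-mean frequency and arithmetic-mean value, the bin
# assignment and the retained raw indices (NA values dropped).
bin_geometric <- function(freqs, values, bins_per_decade = 20) {
  lf <- log10(freqs)
  breaks <- seq(min(lf) - 1e-9, max(lf) + 1 / bins_per_decade,
                by = 1 / bins_per_decade)
  bin <- findInterval(lf, breaks)
  ok <- is.finite(values)
  fb <- tapply(lf[ok], bin[ok], mean)
  vb <- tapply(values[ok], bin[ok], mean)
  list(freqs = 10^as.numeric(fb), values = as.numeric(vb),
       bin = bin, ok = ok, bins_per_decade = bins_per_decade)
}

# average `values` over a previously computed binning (same raw grid/mask)
rebin_like <- function(smoothing, values) {
  ok <- smoothing$ok
  as.numeric(tapply(values[ok], smoothing$bin[ok], mean))
}

#' Dynamical transfer function from STA and stimulus autocorrelation
#'
#' Bin-wise ratio of the discrete Fourier transform of the (mean-centered)
#' spike-triggered average and the stimulus power spectral density (the
#' transform of the autocorrelation), on identical lag grids.  The
#' zero-frequency bin is dropped; PSD bins below machine tolerance are masked
#' rather than divided by.  The magnitude is additionally smoothed by
#' geometric-frequency binning (default 20 bins per decade) for the summary
#' extractors ([cutoff_frequency()], [powerlaw_fit()]), which are otherwise
#' unstable on raw single-bin estimates.
#'
#' @param sta an [compute_sta()] result.
#' @param iac an [autocorrelation()] of the same stimulus on the same lag
#'   grid.
#' @param bins_per_decade magnitude smoothing resolution; `NULL` disables
#'   smoothing.
#' @param psd_rel_tol relative PSD masking tolerance.
#' @return object of class `transfer_function`: `freqs` (cycle/s, 0
#'   excluded), complex `H`, `magnitude`, `phase`, and `smoothing` (binned
#'   `freqs` / `magnitude`).  `threshold` is `NULL` until
#'   [set_significance()] attaches a surrogate curve.
#' @export
estimate_transfer <- function(sta, iac, bins_per_decade = 20,
                              psd_rel_tol = 1e-12) {
  stopifnot(inherits(sta, "sta_result"), inherits(iac, "autocorrelation"))
  if (length(sta$values) != length(iac$values) ||
      !isTRUE(all.equal(sta$dt, iac$dt)))
    stop("`sta` and `iac` must be on identical lag grids")
  ps <- psd_positive(iac, psd_rel_tol)
  S <- stats::fft(lag_wrap(sta$values - mean(sta$values)))[ps$keep]
  H <- S / ps$P
  mag <- Mod(H)
  tf <- structure(list(freqs = ps$freqs, H = H, magnitude = mag,
                       phase = Arg(H), dt = sta$dt, threshold = NULL,
                       smoothing = NULL),
                  class = "transfer_function")
  if (!is.null(bins_per_decade))
    tf$smoothing <- bin_geometric(ps$freqs, mag, bins_per_decade)
  tf
}

#' Construct a transfer-function object from an explicit magnitude curve
#'
#' Mostly for synthetic curves and tests; [estimate_transfer()] is the
#' estimation route.
#'
#' @param freqs strictly increasing frequencies (cycle/s, no 0).
#' @param magnitude non-negative magnitudes, same length.
#' @param threshold optional significance curve on the same grid.
#' @return a `transfer_function` (unsmoothed).
#' @export
transfer_function <- function(freqs, magnitude, threshold = NULL) {
  stopifnot(length(freqs) == length(magnitude), all(diff(freqs) > 0),
            all(freqs > 0))
  structure(list(freqs = freqs, H = as.complex(magnitude),
                 magnitude = magnitude, phase = rep(0, length(freqs)),
                 dt = NA_real_, threshold = threshold, smoothing = NULL),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> %d frequency bins in [%.3g, %.3g] cycle/s%s%s\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              if (!is.null(x$smoothing)) sprintf("; smoothed (%g bins/decade)",
                                                 x$smoothing$bins_per_decade) else "",
              if (!is.null(x$threshold)) "; significance threshold attached" else ""))
  invisible(x)
}

# Summary curve used by the extractors: smoothed when available, raw
# otherwise; NA magnitudes dropped; `sig` marks bins above the surrogate
# threshold (all TRUE when no threshold is attached).
curve_for_summary <- function(tf) {
  if (!is.null(tf$smoothing)) {
    f <- tf$smoothing$freqs
    mag <- tf$smoothing$values
    thr <- tf$smoothing$threshold
  } else {
    ok <- is.finite(tf$magnitude)
    f <- tf$freqs[ok]
    mag <- tf$magnitude[ok]
    thr <- if (!is.null(tf$threshold)) tf$threshold[ok] else NULL
  }
  sig <- if (is.null(thr)) rep(TRUE, length(f)) else mag > thr
  list(f = f, mag = mag, sig = sig)
}

# log-log linear interpolation of a magnitude curve at frequency f0
loglog_interp <- function(f, mag, f0) {
  if (f0 <= f[1]) return(mag[1])
  if (f0 >= f[length(f)]) return(mag[length(mag)])
  exp(stats::approx(log(f), log(mag), xout = log(f0))$y)
}

#' Surrogate-based significance threshold for the transfer magnitude
#'
#' Bootstrap null distribution of `|H(f)|` under within-trial shuffling of
#' the inter-spike intervals (each trial keeps its spike count and first
#' spike time).  For each of `n_surrogates` shuffles the STA analysis is
#' repeated against the same current; the threshold at each frequency is the
#' surrogate mean plus one surrogate standard deviation.
#'
#' @param trials as in [compute_sta()]; every trial needs >= 2 spikes.
#' @param T lag half-window (ms).
#' @param n_surrogates number of shuffles (>= 2); default 500.
#' @param seed RNG seed for reproducible shuffles.
#' @param iac optional precomputed [autocorrelation()] (max_lag = T);
#'   computed from the trial currents otherwise.
#' @param psd_rel_tol PSD masking tolerance, as in [estimate_transfer()].
#' @return object of class `surrogate_threshold`: `freqs`, `mean`, `sd`,
#'   `threshold` (= mean + sd), `n_surrogates`.
#' @export
surrogate_threshold <- function(trials, T = 500, n_surrogates = 500,
                                seed = NULL, iac = NULL,
                                psd_rel_tol = 1e-12) {
  if (n_surrogates < 2) stop("`n_surrogates` must be >= 2")
  if (any(vapply(trials, function(tr) length(tr$spikes$times) < 2L, TRUE)))
    stop("every trial needs >= 2 spikes for ISI shuffling")
  if (is.null(iac))
    iac <- autocorrelation(lapply(trials, `[[`, "current"), max_lag = T)
  ps <- psd_positive(iac, psd_rel_tol)
  nf <- length(ps$freqs)
  s1 <- numeric(nf); s2 <- numeric(nf)
  with_seed(seed, {
    for (s in seq_len(n_surrogates)) {
      sh <- lapply(trials, function(tr) {
        ts <- tr$spikes$times
        isis <- sample(diff(ts))
        list(current = tr$current,
             spikes = spike_train(ts[1] + c(0, cumsum(isis)),
                                  duration = tr$spikes$duration))
      })
      sta_s <- compute_sta(sh, T)
      S <- stats::fft(lag_wrap(sta_s$values - mean(sta_s$values)))[ps$keep]
      mg <- Mod(S / ps$P)
      s1 <- s1 + ifelse(is.na(mg), 0, mg)
      s2 <- s2 + ifelse(is.na(mg), 0, mg^2)
    }
  })
  mu <- s1 / n_surrogates
  sdv <- sqrt(pmax(0, s2 / n_surrogates - mu^2) * n_surrogates / (n_surrogates - 1))
  structure(list(freqs = ps$freqs, mean = mu, sd = sdv,
                 threshold = mu + sdv, n_surrogates = n_surrogates),
            class = "surrogate_threshold")
}

#' Attach a surrogate significance threshold to a transfer function
#'
#' Stores the raw threshold curve and, when the transfer function carries a
#' smoothed magnitude, averages the threshold over the same geometric bins so
#' significant bins can be identified on the smoothed grid.
#'
#' @param tf a `transfer_function` from [estimate_transfer()].
#' @param thr a [surrogate_threshold()] on the same frequency grid.
#' @return the updated `transfer_function`.
#' @export
set_significance <- function(tf, thr) {
  stopifnot(inherits(tf, "transfer_function"),
            inherits(thr, "surrogate_threshold"))
  if (length(tf$freqs) != length(thr$freqs) ||
      max(abs(tf$freqs - thr$freqs)) > 1e-8 * max(tf$freqs))
    stop("threshold and transfer function are on different frequency grids")
  tf$threshold <- thr$threshold
  if (!is.null(tf$smoothing))
    tf$smoothing$threshold <- rebin_like(tf$smoothing, thr$threshold)
  tf
}

#' Encoding cut-off frequency of a transfer function
#'
#' The frequency at which the (significant) transfer magnitude first falls
#' to `fraction` (default 0.7) of its value at `ref_freq` (default 1
#' cycle/s).  Interpolations (the 1-Hz reference and the crossing) are
#' log-log linear; when a significance threshold is attached, only bins above
#' it are considered, and the result is undefined when the reference itself
#' is not significant or no crossing exists within the significant band.
#'
#' @param tf a `transfer_function`.
#' @param ref_freq reference frequency (cycle/s); default 1.
#' @param fraction crossing level; default 0.7.
#' @param criterion `"fraction_of_reference"` (default: magnitude down to
#'   `fraction * ref`) or `"fractional_decrease"` (down by `fraction`, i.e.
#'   to `(1 - fraction) * ref`).
#' @return object of class `cutoff_result`: `f_cut` (cycle/s or NA),
#'   `defined`, `ref_magnitude`, `target`, `reason` (when undefined).
#' @export
cutoff_frequency <- function(tf, ref_freq = 1, fraction = 0.7,
                             criterion = c("fraction_of_reference",
                                           "fractional_decrease")) {
  criterion <- match.arg(criterion)
  cur <- curve_for_summary(tf)
  undefined <- function(reason, ref = NA_real_, target = NA_real_)
    structure(list(f_cut = NA_real_, defined = FALSE, ref_magnitude = ref,
                   target = target, reason = reason),
              class = "cutoff_result")
  if (length(cur$f) < 2L) return(undefined("fewer than 2 usable bins"))
  # reference bin(s) must be significant
  iref <- max(1L, findInterval(ref_freq, cur$f))
  if (!cur$sig[iref] || (iref < length(cur$f) && cur$f[iref] < ref_freq &&
                         !cur$sig[iref + 1L]))
    return(undefined("magnitude not significant at the reference frequency"))
  ref <- loglog_interp(cur$f, cur$mag, ref_freq)
  target <- if (criterion == "fraction_of_reference") fraction * ref
            else (1 - fraction) * ref
  scan <- which(cur$f > ref_freq & cur$sig)
  prev_f <- ref_freq; prev_m <- ref
  for (i in scan) {
    if (cur$mag[i] <= target) {
      if (prev_m <= target || cur$mag[i] == target || prev_f == cur$f[i]) {
        f_cut <- cur$f[i]
      } else {
        w <- (log(prev_m) - log(target)) / (log(prev_m) - log(cur$mag[i]))
        f_cut <- exp(log(prev_f) + w * (log(cur$f[i]) - log(prev_f)))
      }
      return(structure(list(f_cut = f_cut, defined = TRUE,
                            ref_magnitude = ref, target = target,
                            reason = NULL),
                       class = "cutoff_result"))
    }
    prev_f <- cur$f[i]; prev_m <- cur$mag[i]
  }
  undefined("no crossing below the target within the significant band",
            ref, target)
}

#' @export
print.cutoff_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<cutoff_result> f_cut = %.2f cycle/s (reference %.3g, target %.3g)\n",
                x$f_cut, x$ref_magnitude, x$target))
  else
    cat(sprintf("<cutoff_result> undefined: %s\n", x$reason))
  invisible(x)
}

#' High-frequency power-law fit of the transfer magnitude
#'
#' Least-squares fit of `y = b * f^-alpha` (linear in log-log coordinates)
#' over the band from the cut-off frequency down to where the magnitude
#' reaches `stop_fraction` (default 0.2) of its value at the cut-off -- or
#' the last significant bin when that level is never reached.
#'
#' When a significance threshold is attached, the fit uses the contiguous
#' significant band starting at the cut-off: bins past the first
#' non-significant bin are outside the resolvable response profile and are
#' not fitted.
#'
#' @param tf a `transfer_function`.
#' @param f_cut the cut-off frequency (cycle/s), e.g. from
#'   [cutoff_frequency()].
#' @param stop_fraction magnitude level terminating the fit band.
#' @param min_bins minimum number of bins required; default 5.
#' @return list with `b`, `alpha` (positive for a decaying magnitude),
#'   `fit_range` (cycle/s), `n_bins`.
#' @export
powerlaw_fit <- function(tf, f_cut, stop_fraction = 0.2, min_bins = 5) {
  stopifnot_scalar(f_cut, "f_cut", positive = TRUE)
  cur <- curve_for_summary(tf)
  mag_cut <- loglog_interp(cur$f, cur$mag, f_cut)
  idx <- which(cur$f >= f_cut)
  if (!length(idx) || !any(cur$sig[idx]))
    stop("no significant bins above the cut-off")
  # contiguous significant band from the cut-off
  gap <- which(!cur$sig[idx])
  if (length(gap)) idx <- idx[seq_len(gap[1] - 1L)]
  if (!length(idx)) stop("no significant bins above the cut-off")
  below <- which(cur$mag[idx] <= stop_fraction * mag_cut)
  if (length(below)) idx <- idx[seq_len(below[1])]
  if (length(idx) < min_bins)
    stop(sprintf("only %d bins in the fit band (need >= %d)",
                 length(idx), min_bins))
  lf <- log(cur$f[idx]); lm_ <- log(cur$mag[idx])
  fit <- lm(lm_ ~ lf)
  list(b = exp(coef(fit)[[1]]), alpha = -coef(fit)[[2]],
       fit_range = range(cur$f[idx]), n_bins = length(idx))
}

#' Coefficient of variation of the inter-spike intervals
#'
#' Population (1/n) standard deviation of the ISIs divided by their mean; the
#' standard irregularity index of a spike train.
#'
#' @param spikes a [spike_train()] or a numeric ISI vector.
#' @return dimensionless CV.
#' @export
isi_cv <- function(spikes) {
  x <- if (inherits(spikes, "spike_train")) isi(spikes) else as.numeric(spikes)
  if (length(x) < 2L) stop("need >= 2 ISIs")
  pop_sd(x) / mean(x)
}
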