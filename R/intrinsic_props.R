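#' Detect action potentials in a voltage trace
#'
#' Spike times are placed at local voltage maxima following upward crossings
#' of `peak_threshold`; maxima closer than `min_interval` are merged, keeping
#' the larger peak.
#'
#' @param v a [voltage_trace()].
#' @param peak_threshold detection level (mV); default 0.
#' @param min_interval merge window (ms); default 2.
#' @return a [spike_train()] (possibly empty).
#' @export
detect_spikes <- function(v, peak_threshold = 0, min_interval = 2) {
  stopifnot(inherits(v, "voltage_trace"))
  x <- v$values
  n <- length(x)
  above <- x >= peak_threshold
  up <- which(!above[-n] & above[-1]) + 1L     # first sample at/above threshold
  if (!length(up)) return(spike_train(numeric(0), duration = trace_duration(v)))
  down <- which(above[-n] & !above[-1])        # last sample at/above threshold
  peaks <- vapply(up, function(s) {
    e <- down[down >= s][1]
    if (is.na(e)) e <- n
    s - 1L + which.max(x[s:e])
  }, integer(1))
  # merge peaks closer than min_interval, keeping the larger
  min_steps <- round(min_interval / v$dt)
  keep <- integer(0)
  for (p in peaks) {
    if (length(keep) && (p - keep[length(keep)]) < min_steps) {
      if (x[p] > x[keep[length(keep)]]) keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  spike_train((keep - 1L) * v$dt, duration = trace_duration(v))
}

#' Mean voltage over the last part of a step response
#'
#' Steady-state voltage read-out for step protocols: the mean over the final
#' `last_ms` of the trace.
#'
#' @param v a [voltage_trace()].
#' @param last_ms averaging window at the end of the trace (ms); default 200.
#' @return steady-state voltage (mV).
#' @export
steady_state_voltage <- function(v, last_ms = 200) {
  stopifnot(inherits(v, "voltage_trace"))
  n <- length(v$values)
  k <- min(n, max(1L, round(last_ms / v$dt)))
  mean(v$values[(n - k + 1L):n])
}

#' Input resistance from steady-state V-I points
#'
#' Least-squares slope of the steady-state voltage vs injected current line,
#' from hyperpolarizing step responses.
#'
#' @param I injected currents (pA), at least 2 distinct values.
#' @param V steady-state voltages (mV), same length.
#' @return input resistance (MOhm).
#' @export
input_resistance <- function(I, V) {
  if (length(I) != length(V) || length(I) < 2L)
    stop("need >= 2 (I, V) points")
  if (length(unique(I)) < 2L) stop("currents must span a non-zero range")
  slope <- coef(lm(V ~ I))[[2]]           # mV/pA = GOhm
  slope * 1000                            # MOhm
}

#' Membrane time constant from a recovery transient
#'
#' Fits `a + b1 exp(-t/tau1) + b2 exp(-t/tau2)` to the membrane-potential
#' recovery after a brief hyperpolarizing pulse and returns the slowest time
#' constant.  When the bi-exponential fit fails or degenerates, a
#' single-exponential fit is used and the result is flagged.
#'
#' @param recovery a [voltage_trace()] starting at the pulse offset.
#' @return list with `tau_mem` (ms), `method` ("biexp" or "single"),
#'   `flagged` (TRUE when the fallback was used) and the fit coefficients.
#' @export
membrane_time_constant <- function(recovery) {
  stopifnot(inherits(recovery, "voltage_trace"))
  y <- recovery$values
  t <- (seq_along(y) - 1) * recovery$dt
  a0 <- mean(tail(y, max(5L, round(0.1 * length(y)))))
  d0 <- y[1] - a0
  if (abs(d0) < 1e-9) stop("no transient to fit")
  # single-exponential start from the log-linear decay
  rel <- (y - a0) / d0
  sel <- which(rel > 0.05)
  tau0 <- tryCatch(-1 / coef(lm(log(rel[sel]) ~ t[sel]))[[2]],
                   error = function(e) NA)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t) / 5
  # peeling starts: slow component from the tail, fast from the remainder
  peel <- tryCatch(suppressWarnings({
    late <- which(t >= tau0 & rel > 0.02)
    cs <- coef(lm(log(d0 * rel[late]) ~ t[late]))
    tau_s <- -1 / cs[[2]]; b_s <- exp(cs[[1]])
    r <- d0 * rel - b_s * exp(-t / tau_s)
    early <- which(t < tau0 & r * sign(d0) > 0.02 * abs(d0))
    cf <- coef(lm(log(abs(r[early])) ~ t[early]))
    list(tau_s = tau_s, b_s = b_s, tau_f = -1 / cf[[2]],
         b_f = sign(d0) * exp(cf[[1]]))
  }), error = function(e) NULL)
  if (is.null(peel) || !is.finite(peel$tau_f) || peel$tau_f <= 0 ||
      !is.finite(peel$tau_s) || peel$tau_s <= 0)
    peel <- list(tau_s = tau0, b_s = 0.7 * d0, tau_f = tau0 / 5,
                 b_f = 0.3 * d0)
  bi <- tryCatch({
    fit <- minpack.lm::nlsLM(
      y ~ a + b1 * exp(-t / tau1) + b2 * exp(-t / tau2),
      start = list(a = a0, b1 = peel$b_f, b2 = peel$b_s,
                   tau1 = peel$tau_f, tau2 = peel$tau_s),
      lower = c(a = -Inf, b1 = -Inf, b2 = -Inf, tau1 = 1e-3, tau2 = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    p <- coef(fit)
    # degenerate when one amplitude vanishes or a tau runs to the data edge
    if (max(p[["tau1"]], p[["tau2"]]) > 5 * max(t)) stop("tau unconstrained")
    list(tau_mem = max(p[["tau1"]], p[["tau2"]]), method = "biexp",
         flagged = FALSE, coef = p)
  }, error = function(e) NULL)
  if (!is.null(bi)) return(bi)
  fit <- minpack.lm::nlsLM(y ~ a + b * exp(-t / tau),
                           start = list(a = a0, b = d0, tau = tau0),
                           lower = c(a = -Inf, b = -Inf, tau = 1e-3),
                           control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- coef(fit)
  list(tau_mem = p[["tau"]], method = "single", flagged = TRUE, coef = p)
}

#' Membrane capacitance from time constant and input resistance
#'
#' `C = tau_mem / R_in`, with ms / MOhm yielding nF.
#'
#' @param R_in input resistance (MOhm), > 0.
#' @param tau_mem membrane time constant (ms), > 0.
#' @return capacitance (nF).
#' @export
capacitance <- function(R_in, tau_mem) {
  stopifnot_scalar(R_in, "R_in", positive = TRUE)
  stopifnot_scalar(tau_mem, "tau_mem", positive = TRUE)
  tau_mem / R_in
}

#' Peak-aligned average action-potential waveform
#'
#' Averages the voltage around each spike on a window `window` (ms, relative
#' to the peak).  Each spike is re-aligned to the local maximum within
#' +/- 1 ms of its nominal time; spikes whose window exceeds the trace are
#' excluded.  Threshold, onset rapidness and peak amplitude are computed from
#' the averaged waveform where defined (NA and a flag otherwise).
#'
#' @param v a [voltage_trace()].
#' @param spikes a [spike_train()].
#' @param window length-2 window around the peak (ms); default c(-5, 5).
#' @param dvdt_threshold threshold criterion passed to [ap_threshold()]
#'   (mV/ms; default 20).
#' @return object of class `ap_waveform`: `time` (ms, peak at 0), `voltage`
#'   (mV), `dt`, `n_spikes`, `peak_index`, plus `v_threshold`,
#'   `onset_rapidness`, `peak_amplitude` (NA where undefined, with reasons in
#'   `flags`).
#' @export
average_ap <- function(v, spikes, window = c(-5, 5), dvdt_threshold = 20) {
  stopifnot(inherits(v, "voltage_trace"), inherits(spikes, "spike_train"))
  x <- v$values
  n <- length(x)
  dt <- v$dt
  lo <- round(window[1] / dt)
  hi <- round(window[2] / dt)
  realign <- round(1 / dt)
  rows <- list()
  for (tk in spikes$times) {
    k <- round(tk / dt) + 1L
    a <- max(1L, k - realign); b <- min(n, k + realign)
    k <- a - 1L + which.max(x[a:b])
    if (k + lo < 1L || k + hi > n) next
    rows[[length(rows) + 1L]] <- x[(k + lo):(k + hi)]
  }
  if (!length(rows))
    stop("no spike has a full averaging window inside the trace")
  m <- do.call(rbind, rows)
  w <- structure(list(time = seq(lo, hi) * dt,
                      voltage = colMeans(m),
                      dt = dt,
                      n_spikes = nrow(m),
                      peak_index = which(seq(lo, hi) == 0L)),
                 class = "ap_waveform")
  flags <- character(0)
  thr <- tryCatch(ap_threshold(w, dvdt_threshold),
                  error = function(e) { flags <<- c(flags, threshold = conditionMessage(e)); NA_real_ })
  w$v_threshold <- thr
  w$peak_amplitude <- if (is.finite(thr)) w$voltage[w$peak_index] - thr else NA_real_
  rap <- tryCatch(onset_rapidness(w),
                  error = function(e) { flags <<- c(flags, rapidness = conditionMessage(e)); NULL })
  w$onset_rapidness <- if (is.null(rap)) NA_real_ else rap$slope
  w$rapidness_reliable <- if (is.null(rap)) FALSE else rap$reliable
  w$flags <- flags
  w
}

#' @export
print.ap_waveform <- function(x, ...) {
  cat(sprintf("<ap_waveform> %d spikes averaged; peak %.1f mV; threshold %.1f mV; rapidness %.1f /ms\n",
              x$n_spikes, x$voltage[x$peak_index], x$v_threshold,
              x$onset_rapidness))
  invisible(x)
}

# centered-difference dV/dt (mV/ms); endpoints use one-sided differences
dvdt_centered <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

#' Action-potential threshold from the rate-of-rise criterion
#'
#' The AP threshold is the voltage at which the upstroke first reaches
#' `criterion` mV/ms (centered differences, linear interpolation between the
#' bracketing samples).
#'
#' @param w an `ap_waveform` from [average_ap()].
#' @param criterion rate-of-rise criterion (mV/ms); default 20.
#' @return threshold voltage (mV).
#' @export
ap_threshold <- function(w, criterion = 20) {
  stopifnot(inherits(w, "ap_waveform"))
  up <- seq_len(w$peak_index)
  d <- dvdt_centered(w$voltage, w$dt)[up]
  i <- which(d >= criterion)[1]
  if (is.na(i)) stop(sprintf("upstroke never reaches %g mV/ms", criterion))
  if (i == 1L) return(w$voltage[1])
  frac <- (criterion - d[i - 1]) / (d[i] - d[i - 1])
  w$voltage[i - 1] + frac * (w$voltage[i] - w$voltage[i - 1])
}

#' Onset rapidness: phase-plane slope at the AP threshold
#'
#' Slope of the AP trajectory in the phase plane (dV/dt vs V) at the
#' threshold voltage, estimated by a local least-squares line over the
#' upstroke samples within `halfwidth` mV of threshold (more noise-robust
#' than a two-point difference).
#'
#' @param w an `ap_waveform`.
#' @param halfwidth voltage neighborhood around threshold (mV); default 2.
#' @param criterion threshold criterion forwarded to [ap_threshold()].
#' @param max_slope slopes above this (1/ms) are flagged unreliable
#'   (degenerate, near-vertical phase plane); default 100.
#' @return list with `slope` (1/ms), `v_threshold`, `n_points`, `reliable`.
#' @export
onset_rapidness <- function(w, halfwidth = 2, criterion = 20,
                            max_slope = 100) {
  stopifnot(inherits(w, "ap_waveform"))
  thr <- if (!is.null(w$v_threshold) && is.finite(w$v_threshold))
    w$v_threshold else ap_threshold(w, criterion)
  up <- seq_len(w$peak_index)
  V <- w$voltage[up]
  d <- dvdt_centered(w$voltage, w$dt)[up]
  sel <- abs(V - thr) <= halfwidth
  if (sum(sel) < 3L)
    stop("fewer than 3 phase-plane points within the threshold neighborhood")
  fit <- lm(d[sel] ~ V[sel])
  slope <- coef(fit)[[2]]
  list(slope = slope, v_threshold = thr, n_points = sum(sel),
       reliable = is.finite(slope) && slope > 0 && slope <= max_slope)
}

#' Dynamic I-V curve fit of the exponential integrate-and-fire model
#'
#' Estimates the spike-initiation parameters from a fluctuating-current
#' episode.  The transmembrane current is `I_m = i(t) - C dV/dt` per sample;
#' samples within the spike-exclusion window (from `pre_ms` before each AP
#' peak until the voltage first returns below the median subthreshold value,
#' and at least `post_ms` after the peak) are removed; the remainder is
#' binned by voltage and the bin means of `F(V) = -I_m/C` are fitted with
#' \deqn{F(V) = (E_L - V + \Delta_T e^{(V - V_T)/\Delta_T}) / \tau_m .}
#'
#' @param v a [voltage_trace()].
#' @param i the matching [current_trace()].
#' @param C membrane capacitance (pF), e.g. from the passive-property chain
#'   (nF * 1000).
#' @param spikes a [spike_train()] of the episode.
#' @param bin_width voltage bin width (mV); default 1.
#' @param min_per_bin minimum samples per retained bin; default 50.
#' @param pre_ms,post_ms spike-exclusion window (ms before peak / minimum ms
#'   after peak); defaults 1.5 and 10.
#' @param min_bins minimum retained bins, below which the fit is refused;
#'   default 8.
#' @param delta_T_lower lower bound of the slope-factor parameter (mV); a fit
#'   pinned at this bound (leaky-like data) is flagged.
#' @return object of class `dynamic_iv_fit`: `EL_fit` (mV), `tau_m_fit`
#'   (ms), `V_T_fit` (mV), `delta_T_fit` (mV), `rms_residual` (mV/ms),
#'   `capacitance_used` (pF), `n_bins`, `delta_T_pinned`, and the binned
#'   curve (`V_bins`, `F_bins`, `counts`).
#' @export
dynamic_iv <- function(v, i, C, spikes, bin_width = 1, min_per_bin = 50,
                       pre_ms = 1.5, post_ms = 10, min_bins = 8,
                       delta_T_lower = 0.01) {
  stopifnot(inherits(v, "voltage_trace"), inherits(i, "current_trace"),
            inherits(spikes, "spike_train"))
  if (length(v$values) != length(i$values)) stop("v and i must be the same length")
  stopifnot_scalar(C, "C", positive = TRUE)
  dt <- v$dt
  x <- v$values
  n <- length(x)
  d <- dvdt_centered(x, dt)
  excl <- rep(FALSE, n)
  pk <- round(spikes$times / dt) + 1L
  for (k in pk) {
    a <- max(1L, k - round(pre_ms / dt))
    excl[a:min(n, k + round(post_ms / dt))] <- TRUE
  }
  med_sub <- median(x[!excl])
  for (k in pk) {
    b0 <- min(n, k + round(post_ms / dt))
    j <- k + which(x[(k + 1L):n] < med_sub)[1]
    if (is.na(j)) j <- n
    if (j > b0) excl[b0:min(n, j)] <- TRUE
  }
  excl[c(1L, n)] <- TRUE                    # one-sided derivative samples
  keep <- which(!excl)
  if (!length(keep)) stop("spike exclusion removed all samples")
  Fv <- d[keep] - i$values[keep] / C        # pA/pF = mV/ms
  Vv <- x[keep]
  bins <- floor(Vv / bin_width)
  cnt <- table(bins)
  good <- names(cnt)[cnt >= min_per_bin]
  if (length(good) < min_bins)
    stop(sprintf("only %d voltage bins with >= %d samples (need >= %d): fit refused",
                 length(good), min_per_bin, min_bins))
  sel <- bins %in% as.numeric(good)
  Vb <- as.numeric(tapply(Vv[sel], bins[sel], mean))
  Fb <- as.numeric(tapply(Fv[sel], bins[sel], mean))
  cb <- as.numeric(table(bins[sel]))
  o <- order(Vb); Vb <- Vb[o]; Fb <- Fb[o]; cb <- cb[o]
  # starts: linear (leaky) part from the lower half of the voltage range
  lowhalf <- Vb <= median(Vb)
  lfit <- lm(Fb[lowhalf] ~ Vb[lowhalf])
  tau0 <- -1 / coef(lfit)[[2]]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- 30
  EL0 <- coef(lfit)[[1]] * tau0
  if (!is.finite(EL0)) EL0 <- min(Vb)
  fit <- NULL
  for (start in list(
    list(EL = EL0, tau = tau0, VT = as.numeric(quantile(Vb, 0.9)), dT = 1.5),
    list(EL = EL0, tau = tau0, VT = max(Vb) + 2, dT = 3))) {
    fit <- tryCatch(minpack.lm::nlsLM(
      Fb ~ (EL - Vb + dT * exp((Vb - VT) / dT)) / tau,
      start = start,
      lower = c(EL = -150, tau = 0.5, VT = -100, dT = delta_T_lower),
      upper = c(EL = 0, tau = 500, VT = 20, dT = 20),
      weights = cb,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (!is.null(fit)) {
    p <- coef(fit)
    res <- residuals(fit)
    out <- list(EL_fit = p[["EL"]], tau_m_fit = p[["tau"]],
                V_T_fit = p[["VT"]], delta_T_fit = p[["dT"]],
                delta_T_pinned = p[["dT"]] <= delta_T_lower * 1.5)
  } else {
    # purely leaky data: the exponential term is unidentifiable; report the
    # linear fit with the slope factor pinned at its lower bound
    lf <- lm(Fb ~ Vb, weights = cb)
    tau_l <- -1 / coef(lf)[[2]]
    if (tau_l <= 0) stop("dynamic I-V curve is not leaky-decreasing; fit failed")
    res <- residuals(lf)
    out <- list(EL_fit = coef(lf)[[1]] * tau_l, tau_m_fit = tau_l,
                V_T_fit = NA_real_, delta_T_fit = delta_T_lower,
                delta_T_pinned = TRUE)
  }
  structure(c(out, list(rms_residual = sqrt(mean(res^2)),
                        capacitance_used = C,
                        n_bins = length(Vb),
                        V_bins = Vb, F_bins = Fb, counts = cb)),
            class = "dynamic_iv_fit")
}

#' @export
print.dynamic_iv_fit <- function(x, ...) {
  cat(sprintf(paste0("<dynamic_iv_fit> EL = %.1f mV, tau_m = %.1f ms, ",
                     "V_T = %.1f mV, delta_T = %.2f mV%s (%d bins, rms %.3g)\n"),
              x$EL_fit, x$tau_m_fit, x$V_T_fit, x$delta_T_fit,
              if (x$delta_T_pinned) " [pinned]" else "", x$n_bins,
              x$rms_residual))
  invisible(x)
}
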