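#' Integrate-and-fire model parameters
#'
#' Parameter set for the reduced membrane equation
#' \deqn{\tau_m \frac{dV}{dt} = E_L - V + \Delta_T e^{(V - V_T)/\Delta_T} + R\,i(t)}
#' `delta_T = 0` selects the leaky (LIF) limit, where the spike condition is
#' `V >= V_T`; with `delta_T > 0` (EIF) the exponential term drives the
#' upstroke and the spike is cut numerically at `V_spike`.  Defaults mimic
#' the passive properties typical of layer-1 cortical interneurons
#' (R about 184 MOhm, tau_m about 36 ms).
#'
#' @param tau_m membrane time constant (ms).
#' @param R input resistance (MOhm).
#' @param EL resting potential (mV).
#' @param V_T threshold parameter (mV).
#' @param delta_T spike slope factor (mV); 0 = leaky limit.
#' @param V_spike numerical spike-cut voltage (mV); must exceed `V_T`.
#' @param V_reset reset potential (mV); must be below `V_T`.
#' @param t_ref absolute refractory period (ms).
#' @return list of class `if_params`.
#' @export
if_params <- function(tau_m = 36, R = 184, EL = -70, V_T = -50, delta_T = 0,
                      V_spike = -20, V_reset = -70, t_ref = 2) {
  stopifnot_scalar(tau_m, "tau_m", positive = TRUE)
  stopifnot_scalar(R, "R", positive = TRUE)
  stopifnot_scalar(delta_T, "delta_T")
  if (delta_T < 0) stop("`delta_T` must be >= 0")
  if (!(V_reset < V_T && V_T < V_spike))
    stop("parameters must satisfy V_reset < V_T < V_spike")
  if (t_ref < 0) stop("`t_ref` must be >= 0")
  structure(list(tau_m = tau_m, R = R, EL = EL, V_T = V_T, delta_T = delta_T,
                 V_spike = V_spike, V_reset = V_reset, t_ref = t_ref),
            class = "if_params")
}

#' Simulate a leaky / exponential integrate-and-fire neuron
#'
#' Forward-Euler integration of the membrane equation in [if_params()] driven
#' by a sampled current.  A spike is assigned to the first sample at which the
#' voltage reaches the spike condition (no sub-step interpolation); the
#' voltage is then clamped at `V_reset` for `t_ref`.  The exponential
#' argument is capped at `exp_cap` (default 30): beyond it divergence within
#' one step is certain and a spike is emitted immediately, which bounds the
#' term at `delta_T * exp(exp_cap)` and avoids overflow.  The simulation is
#' deterministic given the stimulus.
#'
#' @param params an [if_params()] set.
#' @param stim a [current_trace()]; its `dt` is the integration step.
#' @param V0 initial voltage (mV); default `EL`.
#' @param exp_cap cap on the exponential argument.
#' @return list with `voltage` (a [voltage_trace()]) and `spikes` (a
#'   [spike_train()]); sample k of the voltage is V at time (k-1)*dt.
#' @examples
#' stim <- ou_current(2e4, dt = 0.05, i0 = 250, sigma = 60, seed = 1)
#' out <- simulate_if(if_params(), stim)
#' mean_rate(out$spikes)
#' @export
simulate_if <- function(params, stim, V0 = params$EL, exp_cap = 30) {
  stopifnot(inherits(params, "if_params"), inherits(stim, "current_trace"))
  res <- simulate_if_cpp(stim$values, stim$dt, params$tau_m, params$R,
                         params$EL, params$V_T, params$delta_T,
                         params$V_spike, params$V_reset, params$t_ref,
                         V0, exp_cap)
  list(voltage = voltage_trace(res$V, dt = stim$dt),
       spikes = spike_train(res$spikes, duration = trace_duration(stim)))
}

#' Rectangular step-current protocol
#'
#' One trace per amplitude: optional zero baseline, a rectangular pulse of
#' the stated amplitude and duration, optional zero tail.
#'
#' @param amplitudes pulse amplitudes (pA).
#' @param duration pulse duration (ms); default 1000 (the 1-s f-I step).
#' @param dt sample interval (ms).
#' @param pre_ms,post_ms baseline padding before / after the pulse (ms).
#' @return list of [current_trace()], one per amplitude.
#' @export
step_protocol <- function(amplitudes, duration = 1000, dt = 0.05,
                          pre_ms = 0, post_ms = 0) {
  if (!all(is.finite(amplitudes))) stop("`amplitudes` must be finite")
  n_pre <- round(pre_ms / dt)
  n_on <- round(duration / dt)
  n_post <- round(post_ms / dt)
  lapply(amplitudes, function(a) {
    current_trace(c(numeric(n_pre), rep(a, n_on), numeric(n_post)),
                  dt = dt, i0 = a, sigma = 0)
  })
}

#' Synthetic ISI sequences for the five electrical phenotypes
#'
#' Generates an inter-spike-interval sequence satisfying the defining rule of
#' one of the five firing-pattern classes of layer-1 interneurons, around a
#' base rate of 20 spike/s (mean ISI 50 ms):
#' \describe{
#'   \item{cNAC}{flat ISIs (trend removed, so the fitted slope is 0).}
#'   \item{cAC}{linearly accommodating ISIs with slope > 1 ms per index.}
#'   \item{bNAC}{1-2 initial burst ISIs < 20 ms, then flat.}
#'   \item{cSTUT}{contains stuttering pauses, i.e. ISIs >= 100 ms.}
#'   \item{cIR}{irregular: detrended coefficient of variation fixed at 0.35,
#'     all ISIs < 100 ms.}
#' }
#' The sequences are deterministic given `seed` and are classified back to
#' their generating label by [classify_etype()].
#'
#' @param label one of `"cAC"`, `"cNAC"`, `"bNAC"`, `"cSTUT"`, `"cIR"`.
#' @param base_rate nominal rate (spike/s) of the train; default 20.
#' @param n number of ISIs; default 20.
#' @param seed RNG seed.
#' @return numeric vector of `n` ISIs (ms).
#' @export
synth_classed_isi <- function(label, base_rate = 20, n = 20, seed = NULL) {
  labels <- c("cAC", "cNAC", "bNAC", "cSTUT", "cIR")
  if (!is.character(label) || length(label) != 1L || !(label %in% labels))
    stop("unknown e-type label: must be one of ", paste(labels, collapse = ", "))
  if (n < 5) stop("`n` must be >= 5")
  mean_isi <- 1000 / base_rate
  detrend <- function(x) {
    k <- seq_along(x)
    as.numeric(x - stats::fitted(lm(x ~ k)) + mean(x))
  }
  with_seed(seed, switch(label,
    cNAC = detrend(mean_isi + stats::rnorm(n, 0, 0.02 * mean_isi)),
    cAC = {
      slope <- stats::runif(1, 1.8, 3)
      0.6 * mean_isi + slope * (seq_len(n) - 1) + stats::rnorm(n, 0, 0.01 * mean_isi)
    },
    bNAC = {
      n_burst <- sample(1:2, 1)
      c(stats::runif(n_burst, 8, 18),
        detrend(mean_isi + stats::rnorm(n - n_burst, 0, 0.02 * mean_isi)))
    },
    cSTUT = {
      x <- 0.8 * mean_isi + stats::rnorm(n, 0, 0.04 * mean_isi)
      k <- sample(seq_len(n), 2)
      x[k] <- stats::runif(2, 105, 150)
      x
    },
    cIR = {
      x <- detrend(stats::runif(n, 0.5 * mean_isi, 1.8 * mean_isi))
      dev <- x - mean(x)
      # pin the detrended coefficient of variation at 0.35
      x <- mean(x) + dev * (0.35 * mean(x) / pop_sd(dev))
      pmin(pmax(x, 20.5), 99)
    }))
}

# Stereotyped AP deviation template: exponential upstroke (time constant
# tau_up, so the phase-plane slope at threshold is 1/tau_up) peaking at `amp`
# above baseline, exponential decay with tau_down.  Returns the deviation
# sampled on [-t_pre, t_post] around the peak.
ap_template <- function(dt, amp = 90, tau_up = 0.35, tau_down = 1.2,
                        t_pre = 3, t_post = 4) {
  t <- seq(-round(t_pre / dt), round(t_post / dt)) * dt
  dev <- ifelse(t <= 0, amp * exp(t / tau_up), amp * exp(-t / tau_down))
  list(t = t, dev = dev, peak_index = which(t == 0))
}

#' Synthetic voltage trace with stereotyped action potentials
#'
#' Fixture generator: a constant baseline plus additive Gaussian noise plus a
#' stereotyped AP template (exponential upstroke and downstroke, see
#' Details) pasted at each spike time.  Used to validate spike detection and
#' waveform averaging on known ground truth.
#'
#' @details The template deviation is `amp * exp(t/tau_up)` before the peak
#'   and `amp * exp(-t/tau_down)` after, so the upstroke phase plane
#'   (dV/dt vs V) is a straight line of slope `1/tau_up` and the 20 mV/ms
#'   threshold sits `20 * tau_up` mV above baseline.
#'
#' @param spikes a [spike_train()]; spike times are the template peaks.
#' @param dt sample interval (ms).
#' @param baseline resting level (mV).
#' @param noise_sd additive white Gaussian noise SD (mV).
#' @param seed RNG seed for the noise.
#' @param amp template peak height above baseline (mV).
#' @param tau_up,tau_down upstroke / downstroke time constants (ms).
#' @param t_pre,t_post template extent before / after the peak (ms).
#' @return a [voltage_trace()].
#' @export
synth_voltage_trace <- function(spikes, dt = 0.05, baseline = -65,
                                noise_sd = 0, seed = NULL, amp = 90,
                                tau_up = 0.35, tau_down = 1.2,
                                t_pre = 3, t_post = 4) {
  stopifnot(inherits(spikes, "spike_train"))
  if (length(spikes$times) > 1 &&
      min(diff(spikes$times)) < (t_pre + t_post))
    stop("overlapping AP templates: spike separation must exceed the template width")
  n <- round(spikes$duration / dt)
  tmpl <- ap_template(dt, amp, tau_up, tau_down, t_pre, t_post)
  v <- rep(baseline, n)
  off <- round(tmpl$t / dt)
  for (tk in spikes$times) {
    k <- round(tk / dt) + 1
    idx <- k + off
    ok <- idx >= 1 & idx <= n
    v[idx[ok]] <- baseline + tmpl$dev[ok]
  }
  if (noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  voltage_trace(v, dt = dt)
}
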