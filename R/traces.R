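#' Regularly sampled current trace
#'
#' Container for an injected-current waveform sampled at a fixed interval.
#'
#' @param values numeric vector of currents (pA); must be finite.
#' @param dt sample interval (ms).
#' @param i0,sigma optional DC offset and fluctuation SD (pA) of the stimulus
#'   the trace realizes, kept as metadata.
#' @param tau_corr optional correlation time (ms) of the generating process.
#' @return An object of class `current_trace` with fields `values`, `dt` and
#'   the stimulus metadata.
#' @export
current_trace <- function(values, dt, i0 = NA_real_, sigma = NA_real_,
                          tau_corr = NA_real_) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("`values` must have length >= 1")
  if (!all(is.finite(values))) stop("`values` must be finite")
  structure(list(values = values, dt = dt, i0 = i0, sigma = sigma,
                 tau_corr = tau_corr),
            class = "current_trace")
}

#' Regularly sampled membrane-potential trace
#'
#' @param values numeric vector of membrane potentials (mV).
#' @param dt sample interval (ms).
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(values, dt) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("`values` must have length >= 1")
  if (!all(is.finite(values))) stop("`values` must be finite")
  structure(list(values = values, dt = dt), class = "voltage_trace")
}

#' Spike train
#'
#' Ordered action-potential times on `[0, duration)`.
#'
#' @param times strictly increasing spike times (ms).
#' @param duration trace duration (ms).
#' @return An object of class `spike_train` with fields `times` and
#'   `duration`.
#' @export
spike_train <- function(times, duration) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  times <- as.numeric(times)
  if (length(times) && (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE)))
    stop("`times` must be finite and strictly increasing")
  if (length(times) && (times[1] < 0 || times[length(times)] >= duration))
    stop("`times` must lie in [0, duration)")
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples, dt = %g ms (%.3f s), mean = %.2f pA\n",
              length(x$values), x$dt, length(x$values) * x$dt / 1000,
              mean(x$values)))
  invisible(x)
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples, dt = %g ms, range [%.1f, %.1f] mV\n",
              length(x$values), x$dt, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3f s (%.2f spike/s)\n",
              length(x$times), x$duration / 1000,
              1000 * length(x$times) / x$duration))
  invisible(x)
}

# duration of a sampled trace, ms
trace_duration <- function(x) length(x$values) * x$dt

#' Number of spikes divided by duration, in spike/s
#' @param spikes a [spike_train()].
#' @return mean firing rate (spike/s).
#' @export
mean_rate <- function(spikes) 1000 * length(spikes$times) / spikes$duration

#' Inter-spike intervals of a spike train
#' @param spikes a [spike_train()].
#' @return numeric vector of ISIs (ms).
#' @export
isi <- function(spikes) diff(spikes$times)

#' Write / read a current trace as a two-column CSV (time_ms, current_pA)
#'
#' @param trace a [current_trace()].
#' @param path file path.
#' @return `write_current_csv` returns `path` invisibly; `read_current_csv`
#'   returns a [current_trace()].
#' @export
write_current_csv <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  df <- data.frame(time_ms = (seq_along(trace$values) - 1) * trace$dt,
                   current_pA = trace$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_current_csv
#' @export
read_current_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "current_pA") %in% names(df)))
    stop("expected columns time_ms, current_pA")
  dt <- if (nrow(df) > 1) df$time_ms[2] - df$time_ms[1] else 1
  current_trace(df$current_pA, dt = dt)
}
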