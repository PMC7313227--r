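# Bisection on a monotone non-decreasing evaluator.  Stops when the response
# is within `tol` of `target`; after `max_iter` halvings the midpoint is
# returned with `converged = FALSE` and a warning.
bisect_monotone <- function(f, target, lower, upper, tol, max_iter = 60,
                            what = "response") {
  stopifnot_scalar(target, "target")
  stopifnot_scalar(tol, "tol", positive = TRUE)
  if (!(lower < upper)) stop("`bounds` must satisfy lower < upper")
  f_lo <- f(lower)
  f_hi <- f(upper)
  if (f_lo > target + tol || f_hi < target - tol)
    stop(sprintf("bounds do not bracket the target %s: f(lower) = %.4g, f(upper) = %.4g, target = %.4g",
                 what, f_lo, f_hi, target))
  # an endpoint may already satisfy the tolerance
  if (abs(f_lo - target) <= tol)
    return(list(value = lower, achieved = f_lo, n_iter = 0L, converged = TRUE))
  if (abs(f_hi - target) <= tol)
    return(list(value = upper, achieved = f_hi, n_iter = 0L, converged = TRUE))
  mid <- (lower + upper) / 2
  f_mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    f_mid <- f(mid)
    if (abs(f_mid - target) <= tol)
      return(list(value = mid, achieved = f_mid, n_iter = it, converged = TRUE))
    if (f_mid < target) lower <- mid else upper <- mid
  }
  warning(sprintf("bisection did not reach |%s - target| <= %g in %d iterations",
                  what, tol, max_iter))
  list(value = mid, achieved = f_mid, n_iter = max_iter, converged = FALSE)
}

#' Calibrate the stimulus DC offset to a target firing rate
#'
#' Bisection on a monotone rate evaluator, as used to set the mean firing
#' rate of a simulated (or recorded) neuron before a spike-triggered-average
#' experiment.
#'
#' @param rate_evaluator function mapping a DC offset `i0` (pA) to a mean
#'   firing rate (spike/s); assumed monotone non-decreasing over `bounds`.
#'   Deterministic evaluators (e.g. simulations on frozen noise realizations)
#'   make the search reproducible.
#' @param target_rate target mean rate (spike/s).
#' @param bounds length-2 numeric `(lower, upper)` bracketing the target.
#' @param tol rate tolerance (spike/s); default 0.2.
#' @param max_iter maximum number of halvings.
#' @return list with `value` (the calibrated i0, pA), `achieved` (rate at
#'   `value`), `n_iter` and `converged`.
#' @export
calibrate_dc <- function(rate_evaluator, target_rate, bounds, tol = 0.2,
                         max_iter = 60) {
  bisect_monotone(rate_evaluator, target_rate, bounds[1], bounds[2], tol,
                  max_iter, what = "rate")
}

#' Calibrate the stimulus fluctuation SD to a target membrane-potential SD
#'
#' Bisection on a monotone evaluator mapping the stimulus SD `sigma` (pA) to
#' the standard deviation of the membrane-potential fluctuations (mV);
#' target 4 mV reproduces in-vivo-like subthreshold activity.
#'
#' @param vmstd_evaluator function sigma (pA) -> Vm SD (mV), monotone
#'   non-decreasing over `bounds`.
#' @param target_std target Vm SD (mV); default 4.
#' @param bounds length-2 numeric bracketing the target.
#' @param tol Vm SD tolerance (mV).
#' @param max_iter maximum number of halvings.
#' @return as [calibrate_dc()], with `value` the calibrated sigma (pA).
#' @export
calibrate_sigma <- function(vmstd_evaluator, target_std = 4, bounds,
                            tol = 0.1, max_iter = 60) {
  bisect_monotone(vmstd_evaluator, target_std, bounds[1], bounds[2], tol,
                  max_iter, what = "Vm SD")
}
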