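#' Frequency-current (f-I) curve from step responses
#'
#' Mean firing rate (spike count / step duration) per step amplitude.
#'
#' @param step_responses list of `list(amplitude = <pA>, spikes =
#'   <spike_train>)`, one per 1-s step.
#' @return object of class `fi_curve`: `amplitudes` (pA) and `rates`
#'   (spike/s).
#' @export
fi_curve <- function(step_responses) {
  amps <- vapply(step_responses, function(s) s$amplitude, numeric(1))
  rates <- vapply(step_responses, function(s) mean_rate(s$spikes), numeric(1))
  structure(list(amplitudes = amps, rates = rates), class = "fi_curve")
}

#' Select the reference ~20 spike/s train from a step protocol
#'
#' Returns the ISI sequence of the step whose mean rate is nearest
#' `target`; equidistant ties are broken toward the lower amplitude.  Steps
#' with fewer than 3 spikes are not eligible.
#'
#' @param step_responses as in [fi_curve()].
#' @param target target rate (spike/s); default 20.
#' @return object of class `isi_sequence`: `isis` (ms), `amplitude` (pA),
#'   `rate` (spike/s).
#' @export
select_reference_train <- function(step_responses, target = 20) {
  eligible <- Filter(function(s) length(s$spikes$times) >= 3, step_responses)
  if (!length(eligible)) stop("no step with >= 3 spikes")
  amps <- vapply(eligible, function(s) s$amplitude, numeric(1))
  rates <- vapply(eligible, function(s) mean_rate(s$spikes), numeric(1))
  o <- order(abs(rates - target), amps)   # nearest; ties to lower amplitude
  s <- eligible[[o[1]]]
  structure(list(isis = isi(s$spikes), amplitude = s$amplitude,
                 rate = mean_rate(s$spikes)),
            class = "isi_sequence")
}

as_isis <- function(seq) {
  if (inherits(seq, "isi_sequence")) seq$isis
  else if (inherits(seq, "spike_train")) isi(seq)
  else as.numeric(seq)
}

#' Slope of the best-fit line over an ISI sequence
#'
#' Least-squares slope of ISI value against interval index, in ms per index;
#' the accommodation measure used by the phenotype rules.
#'
#' @param seq an `isi_sequence`, a [spike_train()], or a numeric ISI vector.
#' @return slope (ms per interval index).
#' @export
isi_slope <- function(seq) {
  x <- as_isis(seq)
  if (length(x) < 3L) stop("need >= 3 ISIs")
  k <- seq_along(x)
  coef(lm(x ~ k))[[2]]
}

# coefficient of variation of linearly detrended ISIs (population SD / mean)
isi_irregularity <- function(x) {
  k <- seq_along(x)
  r <- x - fitted(lm(x ~ k))
  pop_sd(r) / mean(x)
}

#' Rule-based electrical phenotype classification
#'
#' Sorts an ISI sequence from a ~20 spike/s step response into one of the
#' five firing-pattern classes of layer-1 interneurons.  Rules are applied in
#' a fixed precedence (structural criteria before global trends):
#' \enumerate{
#'   \item `cSTUT` if any ISI >= `stutter_isi` (100 ms);
#'   \item `bNAC` if the first 1-2 ISIs are < `burst_isi` (20 ms) and the
#'     remaining sequence is flat (|slope| < `slope_thresh`);
#'   \item `cAC` if the full-sequence slope > `slope_thresh` (1 ms/index);
#'   \item `cIR` if the detrended coefficient of variation >
#'     `irregular_cv` (0.25), all ISIs being < 100 ms at this point;
#'   \item `cNAC` otherwise (mostly horizontal ISI line).
#' }
#' All diagnostics are returned so alternative rule orders can be audited.
#'
#' @param seq an `isi_sequence`, [spike_train()], or numeric ISI vector with
#'   at least 5 ISIs.
#' @param slope_thresh accommodation threshold (ms per index); default 1.
#' @param burst_isi initial-burst ISI bound (ms); default 20.
#' @param stutter_isi stuttering pause bound (ms); default 100.
#' @param irregular_cv detrended-CV bound for `cIR`; default 0.25.
#' @return object of class `etype_result`: `label`, `isi_slope`, `max_isi`,
#'   `first_two_isis`, `irregularity`.
#' @export
classify_etype <- function(seq, slope_thresh = 1, burst_isi = 20,
                           stutter_isi = 100, irregular_cv = 0.25) {
  x <- as_isis(seq)
  if (length(x) < 5L) stop("need >= 5 ISIs to classify")
  if (any(x <= 0)) stop("ISIs must be positive")
  slope <- isi_slope(x)
  irr <- isi_irregularity(x)
  n_burst <- 0L
  if (x[1] < burst_isi) n_burst <- if (length(x) > 1 && x[2] < burst_isi) 2L else 1L
  rest_flat <- n_burst > 0L && length(x) - n_burst >= 3L &&
    abs(isi_slope(x[-seq_len(n_burst)])) < slope_thresh
  label <-
    if (max(x) >= stutter_isi) "cSTUT"
    else if (rest_flat) "bNAC"
    else if (slope > slope_thresh) "cAC"
    else if (irr > irregular_cv) "cIR"
    else "cNAC"
  structure(list(label = label, isi_slope = slope, max_isi = max(x),
                 first_two_isis = head(x, 2), irregularity = irr),
            class = "etype_result")
}

#' @export
print.etype_result <- function(x, ...) {
  cat(sprintf("<etype_result> %s (slope %.2f ms/index, max ISI %.1f ms, detrended CV %.2f)\n",
              x$label, x$isi_slope, x$max_isi, x$irregularity))
  invisible(x)
}
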