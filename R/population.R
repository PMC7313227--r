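#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation; the p-value comes from the t-distribution
#' with n - 2 degrees of freedom.  Non-finite pairs are excluded pairwise.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p_value`, `n` (pairs used).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 finite pairs")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Kruskal-Wallis one-way analysis of variance by ranks
#'
#' Rank-based H statistic with tie correction and chi-square p-value with
#' k - 1 degrees of freedom.
#'
#' @param groups list of >= 2 numeric samples, each with >= 2 observations.
#' @return list with `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs >= 2 observations")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

# internal: passive-property protocol on a simulator (hyperpolarizing 1-s
# steps for R_in; 10-ms -150 pA pulse + recovery for tau_m)
measure_passives <- function(model, dt = 0.05,
                             step_amps = seq(-150, -30, by = 30)) {
  passive <- model
  passive$V_T <- 1e6; passive$V_spike <- 1e6 + 1   # keep subthreshold
  class(passive) <- "if_params"
  V <- vapply(step_protocol(step_amps, duration = 1000, dt = dt),
              function(st) steady_state_voltage(simulate_if(passive, st)$voltage),
              numeric(1))
  R_in <- input_resistance(step_amps, V)
  pulse <- step_protocol(-150, duration = 10, dt = dt, post_ms = 400)[[1]]
  vt <- simulate_if(passive, pulse)$voltage
  k0 <- round(10 / dt) + 1L
  rec <- voltage_trace(vt$values[k0:length(vt$values)], dt = dt)
  tm <- membrane_time_constant(rec)
  list(R_in = R_in, tau_mem = tm$tau_mem, C_m = capacitance(R_in, tm$tau_mem),
       tau_flagged = tm$flagged)
}

#' Full single-cell characterization pipeline
#'
#' Chains the whole protocol on one simulated cell: passive properties from
#' hyperpolarizing steps, stimulus calibration (`sigma` to a 4-mV
#' membrane-fluctuation SD, `i0` by bisection to the target rate, both on
#' frozen noise realizations so the search is deterministic), repeated 60-s
#' noisy trials until `n_spikes_min` spikes, spike-triggered-average transfer
#' function with cut-off and power-law summaries, f-I curve and e-type
#' classification, AP waveform and dynamic I-V fit.  Stage failures are
#' flagged per field and never abort the record.  Deterministic given `seed`.
#'
#' @param cell_id identifier stored in the record.
#' @param model an [if_params()] set.
#' @param target_rate desired mean rate (spike/s); default 5.
#' @param seed root seed; per-trial streams are derived from it.
#' @param n_spikes_min spikes to accumulate before the spectral analysis;
#'   default 5000.
#' @param trial_duration duration of each noisy trial (ms); default 60000.
#' @param dt integration and sampling step (ms); default 0.05.
#' @param tau_corr stimulus correlation time (ms); default 5.
#' @param vm_sd_target target membrane-fluctuation SD (mV); default 4.
#' @param T STA lag half-window (ms); default 500.
#' @param n_surrogates surrogate count for the significance threshold; 0
#'   (default) skips the surrogate analysis.
#' @param fi_amplitudes step amplitudes (pA) for the f-I protocol.
#' @param rate_tol calibration tolerance (spike/s).
#' @param i0_bounds,sigma_bounds bisection brackets (pA).
#' @param max_trials hard cap on the number of noisy trials.
#' @return object of class `cell_record` (a named list; see
#'   [as.data.frame.cell_record()]), with a `flags` element naming any
#'   failed stages.
#' @export
run_cell_pipeline <- function(cell_id = "cell01", model = if_params(),
                              target_rate = 5, seed = 1,
                              n_spikes_min = 5000, trial_duration = 60000,
                              dt = 0.05, tau_corr = 5, vm_sd_target = 4,
                              T = 500, n_surrogates = 0,
                              fi_amplitudes = seq(0, 300, by = 30),
                              rate_tol = 0.2, i0_bounds = c(0, 1500),
                              sigma_bounds = c(1, 500), max_trials = 200) {
  flags <- list()
  safe <- function(field, expr) {
    tryCatch(expr, error = function(e) {
      flags[[field]] <<- conditionMessage(e)
      NULL
    })
  }
  rec <- list(cell_id = cell_id, model = model, seed = seed,
              target_rate = target_rate)

  ## passive properties
  pass <- safe("passive", measure_passives(model, dt))
  rec$R_in <- if (is.null(pass)) NA_real_ else pass$R_in
  rec$tau_mem <- if (is.null(pass)) NA_real_ else pass$tau_mem
  rec$C_m <- if (is.null(pass)) NA_real_ else pass$C_m

  ## sigma calibration on a frozen subthreshold realization
  sub <- model
  sub$V_T <- 1e6; sub$V_spike <- 1e6 + 1
  class(sub) <- "if_params"
  n_cal <- round(10000 / dt)
  eta_sd <- generate_unit_ou(n_cal, dt, tau_corr, seed = derive_seed(seed, 900001))
  burn <- round(500 / dt)
  sig_cal <- safe("sigma", calibrate_sigma(function(s) {
    stim <- compose_stimulus(eta_sd, i0 = 0, sigma = s, dt = dt)
    sd(simulate_if(sub, stim)$voltage$values[-seq_len(burn)])
  }, target_std = vm_sd_target, bounds = sigma_bounds, tol = 0.05))
  sigma <- if (is.null(sig_cal)) NA_real_ else sig_cal$value
  rec$sigma <- sigma

  ## DC calibration by bisection on frozen noise
  i0 <- NA_real_
  if (is.finite(sigma)) {
    n_ev <- round(20000 / dt)
    etas <- lapply(1:2, function(r)
      generate_unit_ou(n_ev, dt, tau_corr, seed = derive_seed(seed, 910000 + r)))
    dc_cal <- safe("i0", calibrate_dc(function(i0) {
      spikes <- vapply(etas, function(eta) {
        stim <- compose_stimulus(eta, i0 = i0, sigma = sigma, dt = dt)
        length(simulate_if(model, stim)$spikes$times)
      }, numeric(1))
      sum(spikes) / (length(etas) * n_ev * dt / 1000)
    }, target_rate = target_rate, bounds = i0_bounds, tol = rate_tol))
    i0 <- if (is.null(dc_cal)) NA_real_ else dc_cal$value
  }
  rec$i0 <- i0

  ## noisy trials until enough spikes
  trials <- list()
  if (is.finite(i0)) {
    n_tr <- round(trial_duration / dt)
    total_spikes <- 0L
    j <- 0L
    while (total_spikes < n_spikes_min && j < max_trials) {
      j <- j + 1L
      stim <- ou_current(n_tr, dt, tau_corr, i0 = i0, sigma = sigma,
                         seed = derive_seed(seed, j))
      out <- simulate_if(model, stim)
      trials[[j]] <- list(current = stim, spikes = out$spikes,
                          voltage = out$voltage)
      total_spikes <- total_spikes + length(out$spikes$times)
    }
    if (total_spikes < n_spikes_min)
      flags$trials <- sprintf("only %d spikes in %d trials", total_spikes, j)
  }
  rec$n_trials <- length(trials)
  all_isis <- unlist(lapply(trials, function(tr) isi(tr$spikes)))
  rec$n_spikes <- sum(vapply(trials, function(tr) length(tr$spikes$times), 1L))
  rec$mean_rate <- if (length(trials))
    1000 * rec$n_spikes / (length(trials) * trial_duration) else NA_real_
  rec$isi_cv <- if (length(all_isis) >= 2) isi_cv(all_isis) else NA_real_

  ## spectral analysis
  rec$f_cut <- rec$alpha <- rec$b <- NA_real_
  if (length(trials) && rec$n_spikes > 0) {
    sp_trials <- lapply(trials, function(tr) tr[c("current", "spikes")])
    tf <- safe("transfer", {
      sta <- compute_sta(sp_trials, T)
      iac <- autocorrelation(lapply(trials, `[[`, "current"), max_lag = T)
      tf <- estimate_transfer(sta, iac)
      if (n_surrogates >= 2) {
        thr <- surrogate_threshold(sp_trials, T, n_surrogates,
                                   seed = derive_seed(seed, 920000), iac = iac)
        tf <- set_significance(tf, thr)
      }
      tf
    })
    if (!is.null(tf)) {
      co <- cutoff_frequency(tf)
      if (co$defined) {
        rec$f_cut <- co$f_cut
        pl <- safe("powerlaw", powerlaw_fit(tf, co$f_cut))
        if (!is.null(pl)) { rec$alpha <- pl$alpha; rec$b <- pl$b }
      } else flags$cutoff <- co$reason
    }
  }

  ## f-I curve and e-type
  rec$etype <- NA_character_
  steps <- safe("fi", lapply(
    step_protocol(fi_amplitudes, duration = 1000, dt = dt),
    function(st) list(amplitude = st$i0,
                      spikes = simulate_if(model, st)$spikes)))
  rec$fi <- if (is.null(steps)) NULL else fi_curve(steps)
  if (!is.null(steps)) {
    et <- safe("etype", classify_etype(select_reference_train(steps)))
    if (!is.null(et)) rec$etype <- et$label
  }

  ## AP waveform + dynamic I-V on the first noisy trial
  rec$v_threshold <- rec$onset_rapidness <- rec$delta_T_fit <- NA_real_
  if (length(trials) && length(trials[[1]]$spikes$times) >= 1) {
    w <- safe("waveform", average_ap(trials[[1]]$voltage, trials[[1]]$spikes))
    if (!is.null(w)) {
      rec$v_threshold <- w$v_threshold
      rec$onset_rapidness <- w$onset_rapidness
      for (f in names(w$flags)) flags[[paste0("waveform_", f)]] <- w$flags[[f]]
    }
    if (is.finite(rec$C_m)) {
      div <- safe("dynamic_iv",
                  dynamic_iv(trials[[1]]$voltage, trials[[1]]$current,
                             C = rec$C_m * 1000, spikes = trials[[1]]$spikes))
      if (!is.null(div)) {
        rec$delta_T_fit <- div$delta_T_fit
        if (div$delta_T_pinned) flags$delta_T <- "pinned at lower bound"
      }
    }
  }

  rec$flags <- flags
  structure(rec, class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("<cell_record> %s: rate %.2f spike/s, CV %.2f, f_cut %.1f cycle/s, alpha %.2f, e-type %s\n",
              x$cell_id, x$mean_rate, x$isi_cv, x$f_cut, x$alpha, x$etype))
  if (length(x$flags))
    cat("  flags:", paste(names(x$flags), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a cell record to a one-row data frame
#'
#' @param x a `cell_record`.
#' @param ... unused.
#' @return one-row `data.frame` of the scalar observables.
#' @export
as.data.frame.cell_record <- function(x, ...) {
  data.frame(cell_id = x$cell_id, etype = x$etype,
             target_rate = x$target_rate, mean_rate = x$mean_rate,
             isi_cv = x$isi_cv, R_in = x$R_in, tau_mem = x$tau_mem,
             C_m = x$C_m, sigma = x$sigma, i0 = x$i0,
             n_spikes = x$n_spikes, v_threshold = x$v_threshold,
             onset_rapidness = x$onset_rapidness,
             delta_T_fit = x$delta_T_fit, f_cut = x$f_cut,
             alpha = x$alpha, n_flags = length(x$flags),
             stringsAsFactors = FALSE)
}

#' Population study over a synthetic cell cohort
#'
#' Runs [run_cell_pipeline()] for `n_cells` synthetic cells spanning the
#' requested firing regimes and model classes, then reproduces the
#' population-level analyses: rate vs cut-off, onset rapidness vs cut-off
#' and slope factor vs cut-off Pearson correlations, per-e-type cut-off
#' groups compared by Kruskal-Wallis (1% significance, no multiple-testing
#' correction), cut-off distributions per rate regime, and the distribution
#' of the power-law exponent.  Cells with undefined values are excluded
#' pairwise.  Byte-identical output for identical configuration and seed.
#'
#' @param n_cells number of synthetic cells; default 10.
#' @param rates target rate(s) (spike/s), recycled across cells; default
#'   `c(3, 5, 7)`.
#' @param model_class `"lif"`, `"eif"` or `"mixed"` (alternating).
#' @param seed root seed; cell seeds are derived from it.
#' @param heterogeneity relative SD-like jitter (uniform, +/- this fraction)
#'   applied to each cell's R and tau_m; default 0.15.
#' @param base_model template [if_params()].
#' @param delta_T_eif slope factor used for EIF cells (mV); default 1.5.
#' @param ... forwarded to [run_cell_pipeline()] (e.g. `n_spikes_min`,
#'   `trial_duration`, `n_surrogates`).
#' @return object of class `study_result`: `table` (one row per cell),
#'   `correlations`, `kw_etype`, `fcut_by_rate`, `alpha_summary`,
#'   `provenance`.
#' @export
run_population_study <- function(n_cells = 10, rates = c(3, 5, 7),
                                 model_class = c("lif", "eif", "mixed"),
                                 seed = 1, heterogeneity = 0.15,
                                 base_model = if_params(),
                                 delta_T_eif = 1.5, ...) {
  model_class <- match.arg(model_class)
  targets <- rep_len(rates, n_cells)
  jit <- with_seed(derive_seed(seed, 555),
                   matrix(stats::runif(2 * n_cells, 1 - heterogeneity,
                                       1 + heterogeneity), ncol = 2))
  cells <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    dT <- switch(model_class, lif = 0, eif = delta_T_eif,
                 mixed = if (k %% 2 == 0) delta_T_eif else 0)
    m <- base_model
    m$R <- base_model$R * jit[k, 1]
    m$tau_m <- base_model$tau_m * jit[k, 2]
    m$delta_T <- dT
    class(m) <- "if_params"
    cells[[k]] <- run_cell_pipeline(
      cell_id = sprintf("cell%02d", k), model = m,
      target_rate = targets[k], seed = derive_seed(seed, 1000 + k), ...)
  }
  tab <- do.call(rbind, lapply(cells, as.data.frame))
  corr_or_null <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NULL)
    tryCatch(pearson_corr(x, y), error = function(e) NULL)
  }
  correlations <- list(
    rate_fcut = corr_or_null(tab$mean_rate, tab$f_cut),
    rapidness_fcut = corr_or_null(tab$onset_rapidness, tab$f_cut),
    deltaT_fcut = corr_or_null(tab$delta_T_fit, tab$f_cut))
  groups <- split(tab$f_cut[is.finite(tab$f_cut)],
                  tab$etype[is.finite(tab$f_cut)])
  groups <- Filter(function(g) length(g) >= 2, groups)
  kw <- if (length(groups) >= 2) kruskal_wallis(groups) else NULL
  structure(list(
    table = tab,
    cells = cells,
    correlations = correlations,
    kw_etype = kw,
    fcut_by_rate = split(tab$f_cut, tab$target_rate),
    alpha_summary = c(mean = mean(tab$alpha, na.rm = TRUE),
                      sd = sd(tab$alpha, na.rm = TRUE),
                      n = sum(is.finite(tab$alpha))),
    provenance = list(seed = seed, n_cells = n_cells, rates = rates,
                      model_class = model_class,
                      heterogeneity = heterogeneity)),
    class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d cells (%s), rates %s spike/s\n",
              x$provenance$n_cells, x$provenance$model_class,
              paste(x$provenance$rates, collapse = "/")))
  if (!is.null(x$correlations$rate_fcut))
    cat(sprintf("  rate vs f_cut: rho = %.2f (p = %.3g)\n",
                x$correlations$rate_fcut$rho, x$correlations$rate_fcut$p_value))
  cat(sprintf("  alpha: %.2f +/- %.2f (n = %d)\n", x$alpha_summary[["mean"]],
              x$alpha_summary[["sd"]], x$alpha_summary[["n"]]))
  invisible(x)
}

#' Write a study table as CSV
#'
#' @param study a `study_result` (or its `table`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(study, path) {
  tab <- if (inherits(study, "study_result")) study$table else study
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
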