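# spikedyn

Spike-initiation dynamics and neuronal transfer-function analysis in R.

When a neuron is driven by in-vivo-like fluctuating current, its
instantaneous firing rate tracks temporal modulations of the input like a
low-pass filter. `spikedyn` implements the complete current-clamp analysis
chain used to measure that filter — the *dynamical transfer function* — and
the surrounding electrophysiological characterization:

- **Stimulus**: Ornstein–Uhlenbeck current `i(t) = i0 + σ·η(t)` with
  correlation time τ = 5 ms; bisection calibration of `σ` (to 4-mV membrane
  fluctuations) and `i0` (to a target firing rate).
- **Synthetic neurons**: leaky and exponential integrate-and-fire
  simulators, `τ_m dV/dt = E_L − V + Δ_T e^{(V−V_T)/Δ_T} + R·i(t)`, with
  compiled integration loops.
- **Spectral core**: spike-triggered average `sta(t)` on lags ±500 ms,
  transfer function `H(f) = STA(f)/PSD(f)`, a 500-surrogate ISI-shuffle
  significance threshold (mean + SD), the cut-off frequency where `|H|`
  falls to 70% of its 1-cycle/s value, and the high-frequency power law
  `|H(f)| ≈ b·f^(−α)` fitted above the cut-off.
- **Waveforms and passives**: spike detection, input resistance, slowest
  bi-exponential membrane time constant, capacitance `τ/R`, peak-aligned AP
  averaging, the 20 mV/ms threshold, phase-plane onset rapidness, and the
  dynamic I–V fit of the spike slope factor Δ_T.
- **Phenotypes**: the five-class ISI-pattern classifier (cAC, cNAC, bNAC,
  cSTUT, cIR) from ~20 spike/s step-response trains.
- **Population statistics**: per-cell pipeline and cohort studies with
  Pearson correlations (rate vs cut-off, rapidness vs cut-off, Δ_T vs
  cut-off) and Kruskal–Wallis group comparisons.

## Worked example

```r
library(spikedyn)

## one synthetic cell: exponential integrate-and-fire, target 5 spike/s
cell <- run_cell_pipeline(
  cell_id = "demo-eif", model = if_params(delta_T = 1.5),
  target_rate = 5, seed = 3, n_spikes_min = 2000, n_surrogates = 200)
print(cell)
#> <cell_record> demo-eif: rate 4.71 spike/s, CV 0.68, f_cut 15.4 cycle/s, alpha 0.67, e-type cNAC

## the pieces, individually
stim <- ou_current(n = 2e5, dt = 0.05, tau_corr = 5,
                   i0 = cell$i0, sigma = cell$sigma, seed = 1)
out <- simulate_if(if_params(delta_T = 1.5), stim)
print(out$spikes)
#> <spike_train> 43 spikes over 10.000 s (4.30 spike/s)

classify_etype(synth_classed_isi("cSTUT", seed = 4))
#> <etype_result> cSTUT (slope 0.61 ms/index, max ISI 145.7 ms, detrended CV 0.53)
```

Reading the record: the calibrated stimulus made the model fire irregularly
at 4.7 spike/s (ISI CV 0.68); its transfer magnitude stays within 70% of
the 1-cycle/s reference up to 15.4 cycle/s (the encoding cut-off) and
attenuates as `f^-0.67` above it; the constant-current step response is a
non-accommodating train, hence e-type cNAC. A leaky cell
(`if_params(delta_T = 0)`) run the same way yields a much shallower
high-frequency exponent — with correlated input the LIF response barely
attenuates at high frequency — and `NA` waveform fields with explanatory
flags, since a LIF upstroke never reaches the 20 mV/ms threshold criterion.

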