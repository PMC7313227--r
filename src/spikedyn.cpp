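#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the (exponential) integrate-and-fire membrane
// equation  tau_m dV/dt = EL - V + delta_T exp((V - V_T)/delta_T) + R i(t).
// delta_T == 0 selects the leaky limit, in which the spike condition is
// V >= V_T; with delta_T > 0 the exponential term carries V up to the
// numerical cut V_spike.  The exponential argument is capped at `exp_cap`:
// beyond it the divergence is certain within a step, so a spike is emitted
// immediately instead of overflowing.
// Units: ms, mV, pA, MOhm (MOhm * pA = 1e-3 mV).
// [[Rcpp::export]]
List simulate_if_cpp(NumericVector stim, double dt, double tau_m, double R,
                     double EL, double V_T, double delta_T, double V_spike,
                     double V_reset, double t_ref, double V0, double exp_cap) {
  int n = stim.size();
  NumericVector V(n);
  std::vector<double> spikes;
  double v = V0;
  int ref_left = 0;
  int ref_steps = (int)std::lround(t_ref / dt);
  bool lif = (delta_T <= 0.0);
  double thr = lif ? V_T : V_spike;
  for (int k = 0; k < n; ++k) {
    if (ref_left > 0) {
      v = V_reset;
      V[k] = v;
      --ref_left;
      continue;
    }
    double drive = EL - v + R * stim[k] * 1e-3;
    bool forced = false;
    if (!lif) {
      double arg = (v - V_T) / delta_T;
      if (arg > exp_cap) {
        forced = true;
      } else {
        drive += delta_T * std::exp(arg);
      }
    }
    if (!forced) v += dt / tau_m * drive;
    if (forced || v >= thr) {
      spikes.push_back(k * dt);
      v = V_reset;
      ref_left = ref_steps;
    }
    V[k] = v;
  }
  return List::create(_["V"] = V, _["spikes"] = wrap(spikes));
}

// Sum of current segments around spike samples: out[j + m] accumulates
// x[c - j] for lag j*dt, j in [-m, m] (positive lag = current preceding the
// spike).  Caller guarantees idx - m >= 1 and idx + m <= length(x) (1-based).
// [[Rcpp::export]]
NumericVector sta_sums_cpp(NumericVector x, IntegerVector idx, int m) {
  int L = 2 * m + 1;
  NumericVector out(L);
  for (int k = 0; k < idx.size(); ++k) {
    int c = idx[k] - 1;
    for (int j = -m; j <= m; ++j) out[j + m] += x[c - j];
  }
  return out;
}
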