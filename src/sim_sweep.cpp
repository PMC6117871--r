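#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Phenomenological current-clamp sweep simulator.
//
// Leaky-integrator membrane (resting potential E, input resistance R in
// MOhm, time constant tau in s) driven by a square current step I (pA)
// between sample indices i_on (0-based, inclusive) and i_off (exclusive).
// A slow gate s models the H-current: it activates (tau_sag) during
// hyperpolarizing steps, scales the drive by (1 - sag_frac * s) to produce
// sag, and injects reb_gain * s pA after stimulus offset to produce
// rebound. A spike-triggered adaptation current A (increment adapt_inc pA,
// decay tau_adapt) slows firing. Depolarizing drive may ramp in with
// ramp_frac/ramp_tau (late-spiking phenotype). When V crosses vth during a
// depolarizing step (and I < block, the depolarization-block ceiling) a
// stereotyped spike waveform is played back: linear rise of amp mV over
// t_rise, linear fall to vth - ahp_depth over t_fall, followed by an
// absolute refractory period t_ref. Spike threshold-crossing times are
// returned alongside the trace; they are exact ground truth because
// recording noise is added downstream, not here.

// [[Rcpp::export(name = ".simSweepCpp")]]
List simSweepCpp(double I, int nt, double dt, int i_on, int i_off,
                 double E, double R, double tau,
                 double vth, double amp, double t_rise, double t_fall,
                 double ahp_depth, double t_ref,
                 double adapt_inc, double tau_adapt,
                 double sag_frac, double tau_sag, double reb_gain,
                 double ramp_frac, double ramp_tau,
                 double block, bool spiking_enabled) {
  NumericVector v(nt);
  std::vector<double> spikes;
  double V = E, s = 0.0, A = 0.0;
  int n_rise = std::max(1, (int)std::lround(t_rise / dt));
  int n_fall = std::max(1, (int)std::lround(t_fall / dt));
  int wave_len = n_rise + n_fall;
  int wave_pos = -1;
  int refr_until = -1;
  bool can_spike = spiking_enabled && (I < block);
  for (int i = 0; i < nt; ++i) {
    bool in_step = (i >= i_on && i < i_off);
    double Istep = in_step ? I : 0.0;
    double s_inf = (in_step && I < 0) ? 1.0 : 0.0;
    s += dt * (s_inf - s) / tau_sag;
    A += -dt * A / tau_adapt;
    if (wave_pos >= 0) {
      int k = wave_pos++;
      if (k < n_rise) {
        V = vth + amp * (double)(k + 1) / n_rise;
      } else {
        int k2 = k - n_rise;
        V = vth + amp - (amp + ahp_depth) * (double)(k2 + 1) / n_fall;
      }
      if (wave_pos >= wave_len) {
        wave_pos = -1;
        V = vth - ahp_depth;
      }
      v[i] = V;
      continue;
    }
    double drive = Istep;
    if (in_step && I > 0 && ramp_frac > 0)
      drive *= (1.0 - ramp_frac *
                std::exp(-((double)(i - i_on)) * dt / ramp_tau));
    double Ieff = drive * (1.0 - sag_frac * s) - A;
    if (i >= i_off) Ieff += reb_gain * s;
    double vinf = E + R * Ieff / 1000.0;
    V += dt * (vinf - V) / tau;
    if (can_spike && in_step && I > 0 && V >= vth && i > refr_until) {
      spikes.push_back(i * dt);
      A += adapt_inc;
      wave_pos = 0;
      refr_until = i + wave_len + (int)std::lround(t_ref / dt);
      V = vth;
    }
    v[i] = V;
  }
  return List::create(_["v"] = v, _["spikes"] = wrap(spikes));
}
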