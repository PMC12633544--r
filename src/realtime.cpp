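#include <Rcpp.h>
using namespace Rcpp;

// Per-sample emulation of the embedded device loops. Everything here is
// strictly causal: sample n of any output depends only on inputs 0..n.

// First-order IIR offset remover (DC blocker):
//   y[n] = g * (x[n] - x[n-1]) + a * y[n-1],  g = (1 + a) / 2
// a = exp(-2*pi*fc/fs). Zero DC gain; passband gain ~1 well above fc.
// [[Rcpp::export]]
NumericVector dc_blocker_cpp(NumericVector x, double a) {
  int n = x.size();
  NumericVector y(n);
  double g = (1.0 + a) / 2.0;
  double xm1 = 0.0, ym1 = 0.0;
  for (int i = 0; i < n; i++) {
    double yi = g * (x[i] - xm1) + a * ym1;
    y[i] = yi;
    xm1 = x[i];
    ym1 = yi;
  }
  return y;
}

// Cascade of biquads, direct form II transposed.
// sos: k x 6 matrix, rows (b0, b1, b2, a0, a1, a2) with a0 = 1.
// [[Rcpp::export]]
NumericVector sos_filter_cpp(NumericVector x, NumericMatrix sos) {
  int n = x.size(), k = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < k; s++) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; i++) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// One-pole exponential moving average: y[n] = alpha*x[n] + (1-alpha)*y[n-1].
// [[Rcpp::export]]
NumericVector ema_cpp(NumericVector x, double alpha) {
  int n = x.size();
  NumericVector y(n);
  double ym1 = 0.0;
  for (int i = 0; i < n; i++) {
    ym1 = alpha * x[i] + (1.0 - alpha) * ym1;
    y[i] = ym1;
  }
  return y;
}

// Debounced single-threshold comparator. States are 0 (LOW) / 1 (HIGH).
// Enter HIGH when env >= threshold, return LOW when env < threshold; after
// any flip the state is locked for debounce_s seconds (symmetric interlock).
// init_state / since_flip allow continuation across scheduler segments
// (since_flip < 0 means the interlock is inactive, as at t = 0).
// [[Rcpp::export]]
List classify_cpp(NumericVector env, double fs, double threshold,
                  double debounce_s, int init_state = 0,
                  double since_flip = -1.0) {
  int n = env.size();
  IntegerVector states(n);
  std::vector<int> t_idx;
  std::vector<int> t_dir;
  int s = init_state;
  // index of the last flip on the current sample grid (may be negative)
  bool have_flip = since_flip >= 0.0;
  double last_flip = -since_flip * fs;
  for (int i = 0; i < n; i++) {
    bool free_ = !have_flip || ((double)i - last_flip) / fs >= debounce_s;
    if (free_) {
      if (s == 0 && env[i] >= threshold) {
        s = 1; have_flip = true; last_flip = i;
        t_idx.push_back(i); t_dir.push_back(1);
      } else if (s == 1 && env[i] < threshold) {
        s = 0; have_flip = true; last_flip = i;
        t_idx.push_back(i); t_dir.push_back(-1);
      }
    }
    states[i] = s;
  }
  return List::create(_["states"] = states,
                      _["idx"] = wrap(t_idx),
                      _["dir"] = wrap(t_dir));
}

// Ramped constant-current pulse engine. The pulse train runs continuously at
// freq_baseline while LOW and freq_active while HIGH; each pulse moves the
// amplitude by at most ramp_ma_per_pulse towards the state's target. At a
// state flip the train is re-phased so the first pulse of the new regime
// lands one pulse period after the flip. amp[n] is the amplitude after all
// pulses in the n-th sample interval.
// [[Rcpp::export]]
List ramp_cpp(IntegerVector states, double fs, double baseline, double active,
              double ramp, double freq_active, double freq_baseline,
              double amp0, bool sham, bool keep_pulses) {
  int n = states.size();
  NumericVector amp(n);
  std::vector<double> p_t, p_a;
  double a = amp0, dt = 1.0 / fs;
  int prev = states[0];
  double freq = prev ? freq_active : freq_baseline;
  double npt = 1.0 / freq;  // next pulse time (s from trace start)
  for (int i = 0; i < n; i++) {
    if (states[i] != prev) {
      prev = states[i];
      freq = prev ? freq_active : freq_baseline;
      npt = i * dt + 1.0 / freq;  // re-phase at the switch
    }
    double target = sham ? baseline : (prev ? active : baseline);
    double t_hi = (i + 1) * dt;
    while (npt < t_hi) {
      if (a < target) a = std::min(a + ramp, target);
      else if (a > target) a = std::max(a - ramp, target);
      if (keep_pulses) { p_t.push_back(npt); p_a.push_back(a); }
      npt += 1.0 / freq;
    }
    amp[i] = a;
  }
  return List::create(_["amplitude_ma"] = amp,
                      _["pulse_times_s"] = wrap(p_t),
                      _["pulse_amps_ma"] = wrap(p_a));
}

// Full causal closed loop: sense -> condition -> classify -> stimulate ->
// corrupt sensing. The artefact added at sample n is produced by pulses whose
// amplitude was decided from sensed samples 0..n-1 only. Each pulse
// contributes one signed impulse pair (+gain*I at its sample, -gain*I at the
// next) when biphasic, a single +gain*I impulse otherwise.
// forced_states (same length as neural) overrides the classifier, for
// profiles that classify the motion stream instead of the envelope.
// [[Rcpp::export]]
List closed_loop_cpp(NumericVector neural, double fs,
                     double a_dc, NumericMatrix sos, double alpha,
                     double threshold, double debounce_s,
                     double baseline, double active, double ramp,
                     double freq_active, double freq_baseline,
                     double gain, bool biphasic, bool sham,
                     double amp0, Nullable<IntegerVector> forced_states,
                     int init_state = 0, double since_flip = -1.0) {
  int n = neural.size();
  int k = sos.nrow();
  NumericVector env(n), sensed(n), amp(n), art(n);
  IntegerVector states(n);
  std::vector<int> t_idx, t_dir;

  bool forced = forced_states.isNotNull();
  IntegerVector fstate;
  if (forced) fstate = forced_states.get();

  // chain state
  double g_dc = (1.0 + a_dc) / 2.0, xm1 = 0.0, dym1 = 0.0, ema = 0.0;
  std::vector<double> z1(k, 0.0), z2(k, 0.0);

  // classifier state
  int s = init_state;
  bool have_flip = since_flip >= 0.0;
  double last_flip = -since_flip * fs;

  // stimulation state
  double a_ma = amp0, dt = 1.0 / fs;
  int prev = forced ? fstate[0] : s;
  double freq = prev ? freq_active : freq_baseline;
  double npt = 1.0 / freq;
  double pending = 0.0;  // biphasic recovery impulse for the next sample

  for (int i = 0; i < n; i++) {
    // stimulation state follows the classifier decision up to sample i-1
    int s_now = forced ? fstate[i] : s;
    if (s_now != prev) {
      prev = s_now;
      freq = prev ? freq_active : freq_baseline;
      npt = i * dt + 1.0 / freq;
    }
    double target = sham ? baseline : (prev ? active : baseline);

    // pulses landing in this sample interval
    double contrib = pending;
    pending = 0.0;
    double t_hi = (i + 1) * dt;
    while (npt < t_hi) {
      if (a_ma < target) a_ma = std::min(a_ma + ramp, target);
      else if (a_ma > target) a_ma = std::max(a_ma - ramp, target);
      contrib += gain * a_ma;
      if (biphasic) pending -= gain * a_ma;
      npt += 1.0 / freq;
    }
    art[i] = contrib;
    amp[i] = a_ma;
    sensed[i] = neural[i] + contrib;

    // signal chain on the corrupted sample
    double y = g_dc * (sensed[i] - xm1) + a_dc * dym1;
    xm1 = sensed[i];
    dym1 = y;
    for (int sec = 0; sec < k; sec++) {
      double yi = sos(sec, 0) * y + z1[sec];
      z1[sec] = sos(sec, 1) * y - sos(sec, 4) * yi + z2[sec];
      z2[sec] = sos(sec, 2) * y - sos(sec, 5) * yi;
      y = yi;
    }
    y = std::fabs(y);
    ema = alpha * y + (1.0 - alpha) * ema;
    env[i] = ema;

    // debounced classifier (takes effect from the next sample's pulses)
    bool free_ = !have_flip || ((double)i - last_flip) / fs >= debounce_s;
    if (free_) {
      if (s == 0 && ema >= threshold) {
        s = 1; have_flip = true; last_flip = i;
        if (!forced) { t_idx.push_back(i); t_dir.push_back(1); }
      } else if (s == 1 && ema < threshold) {
        s = 0; have_flip = true; last_flip = i;
        if (!forced) { t_idx.push_back(i); t_dir.push_back(-1); }
      }
    }
    states[i] = forced ? fstate[i] : s;
  }
  return List::create(_["envelope"] = env, _["sensed"] = sensed,
                      _["artefact"] = art, _["amplitude_ma"] = amp,
                      _["states"] = states, _["idx"] = wrap(t_idx),
                      _["dir"] = wrap(t_dir));
}
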