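#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of a current-based leaky integrate-and-fire neuron with
// a single exponential synaptic variable shared by all inputs (the model is
// linear in its inputs). Event times are in ms, sorted ascending; each event
// adds its weight (mV) to the synaptic variable. Membrane noise is an
// Ornstein-Uhlenbeck process with stationary sd sigma_v, driven by R's RNG so
// set.seed() controls reproducibility.
//
// [[Rcpp::export]]
List lif_integrate_cpp(NumericVector event_t_ms, NumericVector event_w_mv,
                       double duration_ms, double dt_ms, double tau_m_ms,
                       double tau_s_ms, double v_rest_mv, double v_thresh_mv,
                       double v_reset_mv, double sigma_v_mv,
                       double refractory_ms, int trace_every) {
  const int n_steps = (int)std::ceil(duration_ms / dt_ms);
  const double g_decay = std::exp(-dt_ms / tau_s_ms);
  const double noise_sd = sigma_v_mv * std::sqrt(2.0 * dt_ms / tau_m_ms);

  double v = v_rest_mv;
  double g = 0.0;
  double refr_until = -1.0;
  int ev = 0;
  const int n_ev = event_t_ms.size();

  std::vector<double> spikes;
  std::vector<double> trace_t, trace_v;
  trace_t.reserve(n_steps / std::max(trace_every, 1) + 2);
  trace_v.reserve(n_steps / std::max(trace_every, 1) + 2);

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt_ms;
    // deliver events falling in [t, t + dt)
    while (ev < n_ev && event_t_ms[ev] < t + dt_ms) {
      if (event_t_ms[ev] >= t) {
        g += event_w_mv[ev];
        ++ev;
      } else {
        ++ev; // late event before window start (shouldn't occur when sorted)
      }
    }
    g *= g_decay;
    if (t >= refr_until) {
      v += (dt_ms / tau_m_ms) * (v_rest_mv - v + g);
      if (sigma_v_mv > 0.0) v += noise_sd * norm_rand();
      if (v >= v_thresh_mv) {
        spikes.push_back(t + dt_ms);
        v = v_reset_mv;
        refr_until = t + dt_ms + refractory_ms;
      }
    } else {
      v = v_reset_mv;
    }
    if (trace_every > 0 && (i % trace_every) == 0) {
      trace_t.push_back(t);
      trace_v.push_back(v);
    }
  }
  return List::create(_["spike_t_ms"] = wrap(spikes),
                      _["trace_t_ms"] = wrap(trace_t),
                      _["trace_v_mv"] = wrap(trace_v));
}
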