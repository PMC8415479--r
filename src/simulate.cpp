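// Izhikevich network simulator with conduction delays and STDP.
//
// Integration follows the reference scheme for the model: 1 ms grid, the
// membrane potential advanced in two 0.5 ms half-steps, the recovery variable
// in one full step.  Spikes are delivered along each synapse after its
// conduction delay.  Excitatory weights evolve under exponential STDP
// (nearest-neighbour pre/post pairing at arrival times) until a freeze time,
// then stay constant; inhibitory weights are never plastic.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".simulate_izhikevich")]]
List simulate_izhikevich(NumericMatrix adjacency, IntegerMatrix delays,
                         NumericVector a, NumericVector b, NumericVector c,
                         NumericVector d, LogicalVector excitatory,
                         int duration_ms, int stdp_freeze_ms,
                         double A_plus, double A_minus,
                         double tau_plus, double tau_minus, double w_max,
                         int noise_mode, double noise_amp, int seed) {
  const int N = adjacency.nrow();
  if (adjacency.ncol() != N) stop("adjacency must be square");

  // edge lists (kept in row-major source order so returned weights map back)
  std::vector<int> esrc, edst, edel;
  std::vector<double> ew;
  std::vector<std::vector<int>> out_edges(N), in_edges(N);
  int max_delay = 1;
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      const double w = adjacency(i, j);
      if (w != 0.0) {
        int dl = delays(i, j);
        if (dl < 1) stop("delays must be >= 1 ms on every link");
        if (dl > max_delay) max_delay = dl;
        out_edges[i].push_back((int)ew.size());
        in_edges[j].push_back((int)ew.size());
        esrc.push_back(i); edst.push_back(j); edel.push_back(dl);
        ew.push_back(w);
      }
    }
  }
  const int E = (int)ew.size();
  const int D = max_delay + 1;
  // pending[t % D] holds edge ids whose spike arrives at time t
  std::vector<std::vector<int>> pending(D);

  std::vector<double> v(N), u(N), I(N, 0.0), last_spike(N, -1e9);
  for (int n = 0; n < N; ++n) { v[n] = -65.0; u[n] = b[n] * v[n]; }

  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, N > 0 ? N - 1 : 0);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector<double> w_freeze(ew);
  bool froze_at_start = (stdp_freeze_ms <= 0);
  if (froze_at_start) w_freeze = ew;

  std::vector<int> fired;
  fired.reserve(N);
  for (int t = 0; t < duration_ms; ++t) {
    const bool plastic = t < stdp_freeze_ms;
    // detect spikes from the previous step's integration
    fired.clear();
    for (int n = 0; n < N; ++n) {
      if (v[n] >= 30.0) {
        fired.push_back(n);
        v[n] = c[n];
        u[n] += d[n];
      }
    }
    for (size_t f = 0; f < fired.size(); ++f) {
      const int n = fired[f];
      spike_id.push_back(n);
      spike_t.push_back((double)t);
      if (plastic) {
        // potentiate excitatory in-synapses whose last pre-spike arrived first
        for (size_t k = 0; k < in_edges[n].size(); ++k) {
          const int e = in_edges[n][k];
          if (!excitatory[esrc[e]]) continue;
          const double arr = last_spike[esrc[e]] + edel[e];
          if (arr <= t && arr > -1e8) {
            ew[e] += A_plus * std::exp(-((double)t - arr) / tau_plus);
            if (ew[e] > w_max) ew[e] = w_max;
          }
        }
      }
      for (size_t k = 0; k < out_edges[n].size(); ++k) {
        const int e = out_edges[n][k];
        pending[(t + edel[e]) % D].push_back(e);
      }
    }
    for (size_t f = 0; f < fired.size(); ++f) last_spike[fired[f]] = (double)t;

    // synaptic input arriving now (+ depression of the arriving synapse)
    std::fill(I.begin(), I.end(), 0.0);
    std::vector<int>& arr_now = pending[t % D];
    for (size_t k = 0; k < arr_now.size(); ++k) {
      const int e = arr_now[k];
      if (plastic && excitatory[esrc[e]] && last_spike[edst[e]] > -1e8) {
        ew[e] -= A_minus * std::exp(-((double)t - last_spike[edst[e]]) / tau_minus);
        if (ew[e] < 0.0) ew[e] = 0.0;
      }
      I[edst[e]] += ew[e];
    }
    arr_now.clear();

    // noise drive
    if (noise_mode == 0) {
      if (N > 0) I[pick(rng)] += noise_amp;
    } else {
      for (int n = 0; n < N; ++n) I[n] += noise_amp * gauss(rng);
    }

    // integrate: two half-steps for v, full step for u
    for (int n = 0; n < N; ++n) {
      double vn = v[n], un = u[n];
      vn += 0.5 * (0.04 * vn * vn + 5.0 * vn + 140.0 - un + I[n]);
      vn += 0.5 * (0.04 * vn * vn + 5.0 * vn + 140.0 - un + I[n]);
      // clamp the Euler overshoot at the 30 mV spike cutoff before updating
      // the recovery variable, so every spike cycle is identical
      if (vn > 30.0) vn = 30.0;
      un += a[n] * (b[n] * vn - un);
      if (!std::isfinite(vn) || !std::isfinite(un))
        stop("non-finite membrane state for neuron %d at t = %d ms", n + 1, t);
      v[n] = vn; u[n] = un;
    }

    if (!froze_at_start && t + 1 == stdp_freeze_ms) w_freeze = ew;
  }
  if (!froze_at_start && duration_ms < stdp_freeze_ms) w_freeze = ew;

  NumericMatrix w_final(N, N), w_at_freeze(N, N);
  for (int e = 0; e < E; ++e) {
    w_final(esrc[e], edst[e]) = ew[e];
    w_at_freeze(esrc[e], edst[e]) = w_freeze[e];
  }
  return List::create(_["spike_id"] = spike_id, _["spike_t"] = spike_t,
                      _["weights_final"] = w_final,
                      _["weights_at_freeze"] = w_at_freeze);
}
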