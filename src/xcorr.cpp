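// Delayed cross-correlation kernel for signed functional connectivity.
//
// For every ordered neuron pair (i, j) the kernel counts, over the whole
// recording, how often j spikes l bins after i (l = 1..max_lag; lag 0 is
// excluded because it carries no direction).  The per-pair lag histogram is
// summarized into one signed scalar: sliding sums over a short window (5
// bins, the width of a synaptic correlation hump) are compared with the
// pair's mean count across lags — a baseline that absorbs co-modulation
// inflating every lag equally, e.g. network bursts.  The dominant deviation
// gives the sign (window peak -> excitatory, window trough -> post-synaptic
// suppression, i.e. inhibitory) and the value is normalized by the geometric
// mean of the two spike counts so it is comparable across firing rates.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

#define XCORR_PEAK_WINDOW 5

// Summarize one pair's lag histogram into a signed strength.
static double summarize_pair(const std::vector<double>& counts,
                             double n_source, double n_target) {
  if (n_source <= 0 || n_target <= 0) return 0.0;
  const int L = (int)counts.size();
  const int w = std::min(XCORR_PEAK_WINDOW, L);
  double base = 0.0;
  for (int l = 0; l < L; ++l) base += counts[l];
  base /= L;
  double s = 0.0;
  for (int l = 0; l < w; ++l) s += counts[l];
  double smax = s, smin = s;
  for (int l = w; l < L; ++l) {
    s += counts[l] - counts[l - w];
    if (s > smax) smax = s;
    if (s < smin) smin = s;
  }
  const double peak = smax - w * base;
  const double trough = smin - w * base;
  const double dev = (peak >= -trough) ? peak : trough;
  return dev / std::sqrt(n_source * n_target);
}

// [[Rcpp::export(name = ".xcorr_cm")]]
NumericMatrix xcorr_cm(IntegerVector ids, NumericVector times_ms,
                       int n_neurons, int max_lag, double bin_ms) {
  const int S = ids.size();
  const int N = n_neurons;
  const int L = max_lag;
  if (L < 1) stop("max_lag must be >= 1");
  // lag-count accumulator, pair-major: counts[(i*N + j)*L + (l-1)]
  std::vector<int> counts((size_t)N * N * L, 0);
  std::vector<double> nspk(N, 0.0);
  std::vector<int> b(S);
  for (int s = 0; s < S; ++s) {
    int id = ids[s];
    if (id < 0 || id >= N) stop("neuron id out of range");
    b[s] = (int)std::floor(times_ms[s] / bin_ms);
    nspk[id] += 1.0;
  }
  for (int s1 = 0; s1 < S; ++s1) {
    const int t1 = b[s1], i = ids[s1];
    for (int s2 = s1 + 1; s2 < S; ++s2) {
      const int lag = b[s2] - t1;
      if (lag > L) break;               // times sorted ascending
      if (lag >= 1) counts[((size_t)i * N + ids[s2]) * L + (lag - 1)]++;
    }
  }
  NumericMatrix cm(N, N);
  std::vector<double> c(L);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      if (i == j) continue;
      const size_t base = ((size_t)i * N + j) * L;
      for (int l = 0; l < L; ++l) c[l] = counts[base + l];
      cm(i, j) = summarize_pair(c, nspk[i], nspk[j]);
    }
  }
  return cm;
}

// Full lag-count array (pairs x lags), for estimator diagnostics.
// [[Rcpp::export(name = ".xcorr_counts")]]
IntegerVector xcorr_counts(IntegerVector ids, NumericVector times_ms,
                           int n_neurons, int max_lag, double bin_ms) {
  const int S = ids.size();
  const int N = n_neurons;
  const int L = max_lag;
  IntegerVector counts((R_xlen_t)N * N * L);
  std::vector<int> b(S);
  for (int s = 0; s < S; ++s) b[s] = (int)std::floor(times_ms[s] / bin_ms);
  for (int s1 = 0; s1 < S; ++s1) {
    const int t1 = b[s1], i = ids[s1];
    for (int s2 = s1 + 1; s2 < S; ++s2) {
      const int lag = b[s2] - t1;
      if (lag > L) break;
      if (lag >= 1) counts[((R_xlen_t)i * N + ids[s2]) * L + (lag - 1)]++;
    }
  }
  counts.attr("dim") = IntegerVector::create(L, N, N);  // [lag, j, i] col-major
  return counts;
}

// Lag histogram for a single ordered pair (source -> target); exposed so the
// shuffle-based method can re-use exactly the estimator's summarization.
// [[Rcpp::export(name = ".xcorr_pair_counts")]]
NumericVector xcorr_pair_counts(NumericVector src_ms, NumericVector tgt_ms,
                                int max_lag, double bin_ms) {
  const int L = max_lag;
  NumericVector counts(L);
  const int n1 = src_ms.size(), n2 = tgt_ms.size();
  int j0 = 0;
  for (int s = 0; s < n1; ++s) {
    const int t1 = (int)std::floor(src_ms[s] / bin_ms);
    while (j0 < n2 && (int)std::floor(tgt_ms[j0] / bin_ms) < t1 + 1) ++j0;
    for (int j = j0; j < n2; ++j) {
      const int lag = (int)std::floor(tgt_ms[j] / bin_ms) - t1;
      if (lag > L) break;
      if (lag >= 1) counts[lag - 1] += 1.0;
    }
  }
  return counts;
}

// [[Rcpp::export(name = ".xcorr_summarize")]]
double xcorr_summarize(NumericVector counts, double n_source, double n_target) {
  std::vector<double> c(counts.begin(), counts.end());
  return summarize_pair(c, n_source, n_target);
}
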