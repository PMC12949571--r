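#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Trial-shuffle null for the pooled-population maximum ISI.
//
// Spikes are given delay-relative (within [0, trial_len) of their trial).
// Each iteration independently permutes, per unit, the assignment of that
// unit's spike trains to trial slots and computes the maximum successive ISI
// of the pooled concatenated stream. The maximum gap is found in linear time
// by the pigeonhole method: with 2(n-1) uniform buckets over [min, max] the
// bucket width is at most half the maximum gap, so the maximum gap always
// spans a bucket boundary and equals the largest (next bucket min - previous
// bucket max) over occupied buckets. Uses R's RNG so set.seed() governs
// reproducibility. unit/trial are 0-based per spike.
// [[Rcpp::export]]
NumericVector cpp_shuffle_max_isi(NumericVector time, IntegerVector unit,
                                  IntegerVector trial, int n_units,
                                  int n_trials, double trial_len, int n_iter) {
  const int n = time.size();
  NumericVector out(n_iter);
  if (n < 2) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  std::vector<int> perm(n_units * n_trials);
  std::vector<double> pooled(n);
  const int nb = 2 * (n - 1);
  std::vector<double> bmin(nb), bmax(nb);
  std::vector<int> btag(nb, -1);

  for (int it = 0; it < n_iter; ++it) {
    for (int u = 0; u < n_units; ++u) {
      int* p = &perm[u * n_trials];
      for (int k = 0; k < n_trials; ++k) p[k] = k;
      for (int k = n_trials - 1; k > 0; --k) {  // Fisher-Yates
        int j = (int)(unif_rand() * (k + 1));
        if (j > k) j = k;
        std::swap(p[k], p[j]);
      }
    }
    double vmin = R_PosInf, vmax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double v = time[i] + trial_len * perm[unit[i] * n_trials + trial[i]];
      pooled[i] = v;
      if (v < vmin) vmin = v;
      if (v > vmax) vmax = v;
    }
    if (vmax <= vmin) { out[it] = 0.0; continue; }
    const double inv_w = nb / (vmax - vmin);
    for (int i = 0; i < n; ++i) {
      int b = (int)((pooled[i] - vmin) * inv_w);
      if (b >= nb) b = nb - 1;
      if (btag[b] != it) {
        btag[b] = it;
        bmin[b] = bmax[b] = pooled[i];
      } else {
        if (pooled[i] < bmin[b]) bmin[b] = pooled[i];
        if (pooled[i] > bmax[b]) bmax[b] = pooled[i];
      }
    }
    double mx = 0.0, prev_max = 0.0;
    bool seen = false;
    for (int b = 0; b < nb; ++b) {
      if (btag[b] != it) continue;
      if (seen) {
        double d = bmin[b] - prev_max;
        if (d > mx) mx = d;
      }
      prev_max = bmax[b];
      seen = true;
    }
    out[it] = mx;
  }
  return out;
}
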