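// O(duration) sliding scans of the window-position metrics over all
// candidate window starts {0, ..., duration - length} at 1 ms steps.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// spike count in [s, s+L) for every start s
// [[Rcpp::export]]
IntegerVector cpp_scan_counts(IntegerVector spikes, int L, int D) {
  int ns = D - L + 1;
  IntegerVector out(ns);
  int n = spikes.size(), lo = 0, hi = 0;
  for (int s = 0; s < ns; ++s) {
    while (lo < n && spikes[lo] < s) ++lo;
    if (hi < lo) hi = lo;
    while (hi < n && spikes[hi] < s + L) ++hi;
    out[s] = hi - lo;
  }
  return out;
}

// mean IFF over inter-spike intervals fully contained in [s, s+L):
// pair i contributes iff t0[i] >= s and t1[i] <= s+L-1. Pairs are sorted
// in both endpoints, so the contained set is a contiguous run.
// [[Rcpp::export]]
NumericVector cpp_scan_mean_iff(IntegerVector t0, IntegerVector t1,
                                NumericVector v, int L, int D) {
  int ns = D - L + 1, n = v.size();
  NumericVector cs(n + 1);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + v[i];
  NumericVector out(ns);
  int lo = 0, hi = 0; // run is [lo, hi)
  for (int s = 0; s < ns; ++s) {
    while (lo < n && t0[lo] < s) ++lo;
    if (hi < lo) hi = lo;
    while (hi < n && t1[hi] <= s + L - 1) ++hi;
    out[s] = hi > lo ? (cs[hi] - cs[lo]) / (hi - lo) : 0.0;
  }
  return out;
}

// coefficient of variation (sample sd / mean) of a trace within each
// window; 0 where the window mean is 0. Running sums are refreshed from
// scratch every 1024 starts to bound floating-point drift, and a cv
// below 1e-6 (pure drift residue on constant windows) is clamped to 0.
// [[Rcpp::export]]
NumericVector cpp_scan_cv(NumericVector x, int L) {
  int D = x.size(), ns = D - L + 1;
  NumericVector out(ns);
  double s1 = 0, s2 = 0;
  for (int t = 0; t < L; ++t) { s1 += x[t]; s2 += x[t] * x[t]; }
  for (int s = 0; s < ns; ++s) {
    if (s > 0 && s % 1024 == 0) {
      s1 = 0; s2 = 0;
      for (int t = s; t < s + L; ++t) { s1 += x[t]; s2 += x[t] * x[t]; }
    }
    double mean = s1 / L;
    if (mean > 0 && L > 1) {
      double var = (s2 - s1 * s1 / L) / (L - 1);
      double cv = var > 0 ? std::sqrt(var) / mean : 0.0;
      out[s] = cv < 1e-6 ? 0.0 : cv;
    }
    if (s + 1 < ns) {
      s1 += x[s + L] - x[s];
      s2 += x[s + L] * x[s + L] - x[s] * x[s];
    }
  }
  return out;
}

// Shannon entropy (natural log) of the trace's empirical histogram with
// fixed-width bins (bin 0 holds zero rates) within each window,
// maintained incrementally: H = log(L) - sum(n log n)/L
// [[Rcpp::export]]
NumericVector cpp_scan_entropy(NumericVector x, int L, double bin_width) {
  int D = x.size(), ns = D - L + 1;
  NumericVector out(ns);
  std::vector<int> bin(D);
  int maxbin = 0;
  for (int t = 0; t < D; ++t) {
    bin[t] = (int)std::floor(x[t] / bin_width);
    if (bin[t] > maxbin) maxbin = bin[t];
  }
  std::vector<int> cnt(maxbin + 1, 0);
  auto nlogn = [](int n) { return n > 0 ? n * std::log((double)n) : 0.0; };
  double S = 0;
  for (int t = 0; t < L; ++t) {
    S -= nlogn(cnt[bin[t]]);
    ++cnt[bin[t]];
    S += nlogn(cnt[bin[t]]);
  }
  double logL = std::log((double)L);
  for (int s = 0; s < ns; ++s) {
    // counts are exact; refresh the n*log(n) accumulator periodically to
    // bound floating-point drift from incremental updates
    if (s > 0 && s % 1024 == 0) {
      S = 0;
      for (int b = 0; b <= maxbin; ++b) S += nlogn(cnt[b]);
    }
    double H = logL - S / L;
    out[s] = H > 0 ? H : 0.0;
    if (s + 1 < ns) {
      int bout = bin[s], bin_ = bin[s + L];
      S -= nlogn(cnt[bout]); --cnt[bout]; S += nlogn(cnt[bout]);
      S -= nlogn(cnt[bin_]); ++cnt[bin_]; S += nlogn(cnt[bin_]);
    }
  }
  return out;
}
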