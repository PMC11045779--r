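// Sliding log-odds PWM scan over integer-coded sequences (0..3 = A,C,G,T,
// 4 = N). Windows containing N are skipped. Returns all windows scoring at
// or above `min_score`.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_scan_pwm(List seq_codes, NumericMatrix score, double min_score) {
  const int W = score.nrow();
  std::vector<int> out_seq, out_pos;
  std::vector<double> out_score;
  for (int s = 0; s < seq_codes.size(); ++s) {
    IntegerVector codes = seq_codes[s];
    const int L = codes.size();
    for (int i = 0; i + W <= L; ++i) {
      double sc = 0.0;
      bool ok = true;
      for (int j = 0; j < W; ++j) {
        const int c = codes[i + j];
        if (c < 0 || c > 3) { ok = false; break; }
        sc += score(j, c);
      }
      if (ok && sc >= min_score) {
        out_seq.push_back(s + 1);
        out_pos.push_back(i);
        out_score.push_back(sc);
      }
    }
  }
  return List::create(_["seq"] = wrap(out_seq), _["pos"] = wrap(out_pos),
                      _["score"] = wrap(out_score));
}

// Sliding-window sums of per-position importance with greedy non-overlap
// resolution are done in R; this helper computes, for `reps` random
// permutations of each track, the (1 - fdr) quantile of |window sum| to act
// as the track's null threshold.
// [[Rcpp::export]]
NumericVector cpp_null_threshold(NumericMatrix tracks, int window, int reps,
                                 double fdr, int seed) {
  const int L = tracks.nrow(), N = tracks.ncol();
  NumericVector thr(N);
  std::mt19937 rng((unsigned)seed);
  std::vector<double> v(L), null_sums;
  for (int t = 0; t < N; ++t) {
    for (int i = 0; i < L; ++i) v[i] = tracks(i, t);
    null_sums.clear();
    null_sums.reserve((size_t)reps * (L - window + 1));
    for (int r = 0; r < reps; ++r) {
      std::shuffle(v.begin(), v.end(), rng);
      double s = 0.0;
      for (int i = 0; i < window; ++i) s += v[i];
      null_sums.push_back(std::fabs(s));
      for (int i = window; i < L; ++i) {
        s += v[i] - v[i - window];
        null_sums.push_back(std::fabs(s));
      }
    }
    // type-7 quantile at 1 - fdr
    std::sort(null_sums.begin(), null_sums.end());
    const double h = (null_sums.size() - 1) * (1.0 - fdr);
    const size_t lo = (size_t)std::floor(h);
    const double frac = h - lo;
    thr[t] = null_sums[lo] +
      (lo + 1 < null_sums.size() ? frac * (null_sums[lo + 1] - null_sums[lo]) : 0.0);
  }
  return thr;
}
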