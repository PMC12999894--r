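// Shared O(N^2) template-matching pass for approximate and sample entropy.
// Chebyshev distance, embedding dimension m, absolute radius r.
// ApEn counts include the self-match; SampEn counts exclude it and use the
// N-m templates common to both embedding lengths.
//
// Candidate pairs are pruned by sorting on the first template coordinate:
// a pair can only match when its first coordinates are within r, so only
// those pairs are checked in full. Counts are identical to the naive
// double loop.

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// [[Rcpp::export(name = ".apen_sampen")]]
List apen_sampen(const NumericVector& x, int m, double r) {
  const int N = x.size();
  const int nm = N - m + 1;   // templates of length m
  const int nm1 = N - m;      // templates of length m+1

  std::vector<double> cm(nm, 1.0);    // self-match included
  std::vector<double> cm1(nm1, 1.0);
  double A = 0.0, B = 0.0;

  std::vector<int> ord(nm);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  for (int a = 0; a < nm; ++a) {
    const int i = ord[a];
    for (int b = a + 1; b < nm; ++b) {
      const int j = ord[b];
      if (x[j] - x[i] > r) break;     // sorted: no later b can match
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      cm[i] += 1.0;
      cm[j] += 1.0;
      if (i < nm1 && j < nm1) {
        B += 1.0;
        double d2 = std::fabs(x[i + m] - x[j + m]);
        if (d2 > d) d = d2;
        if (d <= r) {
          A += 1.0;
          cm1[i] += 1.0;
          cm1[j] += 1.0;
        }
      }
    }
  }

  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nm; ++i) phi_m += std::log(cm[i] / nm);
  phi_m /= nm;
  for (int i = 0; i < nm1; ++i) phi_m1 += std::log(cm1[i] / nm1);
  phi_m1 /= nm1;

  return List::create(
      _["apen"] = phi_m - phi_m1,
      _["A"] = A,
      _["B"] = B);
}
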