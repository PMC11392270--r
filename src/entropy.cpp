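#include <Rcpp.h>
using namespace Rcpp;

// Count template matches for sample entropy.
//
// Counting convention (mirrored by the brute-force R oracle in the tests):
// unordered pairs i != j; length-m templates indexed over [1, N-m+1],
// length-(m+1) templates over [1, N-m]; Chebyshev distance; match if d <= r.
// [[Rcpp::export(rng = false)]]
List se_match_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n <= m + 1) stop("series too short for embedding dimension m");
  const int nm = n - m;        // 0-based: templates of length m+1 start at 0..nm-1
  double cm = 0.0, cm1 = 0.0;
  const double *p = REAL(x);
  for (int i = 0; i <= nm; ++i) {          // length-m templates: 0..n-m
    for (int j = i + 1; j <= nm; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        double d = p[i + k] - p[j + k];
        if (d < 0) d = -d;
        if (d > r) { match = false; break; }
      }
      if (!match) continue;
      cm += 1.0;
      if (i < nm && j < nm) {              // both extendable to length m+1
        double d = p[i + m] - p[j + m];
        if (d < 0) d = -d;
        if (d <= r) cm1 += 1.0;
      }
    }
  }
  return List::create(_["c_m"] = cm, _["c_m1"] = cm1);
}
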