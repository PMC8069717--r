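#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman-Moorman convention):
// the n - m templates of length m that have a continuation point are
// compared pairwise (i < j, self-matches excluded) under the Chebyshev
// metric; B counts m-matches, A counts those that also match at index m.
//
// Enumerated lag-wise: for a fixed lag d the Chebyshev test over a
// template is a run of m consecutive pointwise matches |x[t]-x[t+d]| <= r,
// so a single run-length sweep per lag yields every template pair at that
// lag with sequential memory access.
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const double* p = REAL(x);
  double A = 0.0, B = 0.0;
  for (int d = 1; d <= n - 1 - m; ++d) {
    const int imax = n - 1 - m - d;  // largest valid template start i
    if (imax < 0) break;
    int run = 0;
    for (int t = 0; t <= imax + m; ++t) {
      run = (std::abs(p[t] - p[t + d]) <= r) ? run + 1 : 0;
      // template pair (i, i+d) with i = t-m+1 matches over length m
      if (run >= m && t <= imax + m - 1) B += 1.0;
      // extended match over length m+1 for i = t-m
      if (run >= m + 1 && t - m <= imax) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
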