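#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman convention):
// the first n - m points index both the m- and (m+1)-length templates, so
// A/B is a true conditional probability. Chebyshev distance, self-matches
// excluded, each unordered pair counted once.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  double A = 0.0, B = 0.0;
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::abs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > r) break;
      }
      if (d <= r) {
        B += 1.0;
        if (std::abs(x[i + m] - x[j + m]) <= r && d <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
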