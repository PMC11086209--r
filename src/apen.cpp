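#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Approximate entropy with Chebyshev distance and self-matches included:
// ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r), where
// Phi_m(r) = mean_i log( #{ j : max_k |x[i+k] - x[j+k]| <= r } / (N - m + 1) ).
static double phi(const NumericVector& x, int m, double r) {
  const int n = x.size() - m + 1;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int count = 0;
    for (int j = 0; j < n; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) ++count;
    }
    acc += std::log((double)count / (double)n);
  }
  return acc / n;
}

// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  return phi(x, m, r) - phi(x, m + 1, r);
}
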