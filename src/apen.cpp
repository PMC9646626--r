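#include <Rcpp.h>
using namespace Rcpp;

// Approximate entropy, Pincus definition: ApEn = Phi_m(r) - Phi_{m+1}(r),
// Phi_m = mean_i log( C_i^m(r) ), C_i^m = (# j : max_k |x[i+k]-x[j+k]| <= r) / (N-m+1),
// self-matches included, Chebyshev distance. O(n^2 * m).
static double phi(const NumericVector& x, int m, double r) {
  const int n = x.size();
  const int N = n - m + 1;
  if (N <= 0) return 0.0;
  double s = 0.0;
  for (int i = 0; i < N; ++i) {
    int cnt = 0;
    for (int j = 0; j < N; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d > r) break;
      }
      if (d <= r) ++cnt;
    }
    s += std::log(static_cast<double>(cnt) / N);
  }
  return s / N;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  if (r <= 0.0) return 0.0;
  return phi(x, m, r) - phi(x, m + 1, r);
}
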