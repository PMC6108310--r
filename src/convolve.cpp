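#include <Rcpp.h>
using namespace Rcpp;

// Direct discrete convolution of a mass vector with a (short) kernel:
// out[k] = sum_i x[k - i] * w[i], out length n + m - 1. Faster than FFT
// for the short nondecision kernels used here, and exactly mass-preserving.
// [[Rcpp::export]]
NumericVector convolve_masses_cpp(NumericVector x, NumericVector w) {
  const int n = x.size(), m = w.size();
  NumericVector out(n + m - 1);
  for (int i = 0; i < m; ++i) {
    const double wi = w[i];
    if (wi == 0.0) continue;
    for (int j = 0; j < n; ++j) out[i + j] += wi * x[j];
  }
  return out;
}
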