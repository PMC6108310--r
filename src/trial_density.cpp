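#include <Rcpp.h>
using namespace Rcpp;

// Response-time density at arbitrary times: continuous convolution of the
// first-passage density (piecewise-linear in the per-step masses f at bin
// midpoints (j + 0.5) * dt) with a discretized nondecision kernel (mass
// w[i] at (i + 0.5) * dt). Equivalent to grid convolution followed by
// linear interpolation up to O(dt^2).
// [[Rcpp::export]]
NumericVector trial_density_cpp(NumericVector f, double dt, NumericVector w,
                                NumericVector t) {
  const int n = f.size(), m = w.size(), q = t.size();
  NumericVector out(q);
  for (int k = 0; k < q; ++k) {
    double acc = 0.0;
    for (int i = 0; i < m; ++i) {
      if (w[i] == 0.0) continue;
      double s = t[k] - (i + 0.5) * dt;   // decision-time coordinate
      double pos = s / dt - 0.5;          // fractional midpoint index
      if (pos <= -1.0 || pos >= n) continue;
      int j = (int)std::floor(pos);
      double frac = pos - j;
      double flo = (j >= 0 && j < n) ? f[j] : 0.0;
      double fhi = (j + 1 >= 0 && j + 1 < n) ? f[j + 1] : 0.0;
      acc += w[i] * ((1.0 - frac) * flo + frac * fhi);
    }
    out[k] = acc / dt;                    // mass -> density
  }
  return out;
}
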