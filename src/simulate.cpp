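// Exact Ornstein-Uhlenbeck transition sampling along a piecewise-constant
// attractor schedule. Uses R's RNG so seeded runs are reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// z_t = c_t + a_t (z_{t-1} - c_t) + N(0, s_t^2), independently in x and y.
// a, s are per-step lag-one autocorrelation and innovation SD (they encode
// the regime: ranging vs resource visit); cx, cy the attractor schedule.
// [[Rcpp::export]]
NumericMatrix sim_ou_path(const NumericVector& cx, const NumericVector& cy,
                          const NumericVector& a, const NumericVector& s,
                          double x0, double y0) {
  const int n = cx.size();
  NumericMatrix out(n, 2);
  double x = x0, y = y0;
  out(0, 0) = x; out(0, 1) = y;
  for (int t = 1; t < n; ++t) {
    x = cx[t] + a[t] * (x - cx[t]) + R::rnorm(0.0, s[t]);
    y = cy[t] + a[t] * (y - cy[t]) + R::rnorm(0.0, s[t]);
    out(t, 0) = x; out(t, 1) = y;
  }
  return out;
}
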