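#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with explicit initial state.
// b, a are transfer-function coefficients padded to equal length n
// (a[0] == 1); zi has length n - 1. Returns the filtered signal and the
// final state so passes can be chained.
// [[Rcpp::export]]
List iir_df2t(NumericVector b, NumericVector a, NumericVector x,
              NumericVector zi) {
  int n = b.size();
  if (a.size() != n) stop("b and a must have equal length");
  if (zi.size() != n - 1) stop("zi must have length(b) - 1 elements");
  int m = x.size();
  NumericVector y(m);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < m; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (n > 1 ? z[0] : 0.0);
    for (int k = 0; k < n - 2; ++k) {
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    }
    if (n > 1) z[n - 2] = b[n - 1] * xi - a[n - 1] * yi;
    y[i] = yi;
  }
  return List::create(_["y"] = y, _["zf"] = NumericVector(z.begin(), z.end()));
}

// Centered moving average with window w (odd recommended); edges use the
// partial window. Used by the QRS envelope.
// [[Rcpp::export]]
NumericVector moving_average_centered(NumericVector x, int w) {
  int n = x.size();
  if (w < 1) stop("window must be >= 1");
  NumericVector out(n);
  int h = w / 2;
  double acc = 0.0;
  // prefix sums for O(n)
  std::vector<double> ps(n + 1, 0.0);
  for (int i = 0; i < n; ++i) ps[i + 1] = ps[i] + x[i];
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - h);
    int hi = std::min(n - 1, i + h);
    acc = ps[hi + 1] - ps[lo];
    out[i] = acc / (hi - lo + 1);
  }
  return out;
}
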