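#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Cascade of biquad sections (rows of `sos`: b0 b1 b2 a0 a1 a2, a0 == 1),
// transposed direct form II. Initial conditions per section are the
// steady-state response to a constant input equal to the first sample,
// which suppresses start-up transients (same convention as common
// sosfiltfilt implementations).
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  int ns = sos.nrow();
  int n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    // steady-state zi for unit step: solve (I - A) z = B with
    // A = [[-a1, 1], [-a2, 0]], B = [b1 - a1*b0, b2 - a2*b0]
    double B1 = b1 - a1 * b0, B2 = b2 - a2 * b0;
    // (1 + a1) z1 - z2 = B1 ; a2 z1 + z2 = B2  =>
    double det = (1.0 + a1) + a2;
    double z1_0, z2_0;
    if (det != 0.0) {
      z1_0 = (B1 + B2) / det;
      z2_0 = B2 - a2 * z1_0;
    } else {
      z1_0 = z2_0 = 0.0;
    }
    double z1 = z1_0 * y[0], z2 = z2_0 * y[0];
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
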