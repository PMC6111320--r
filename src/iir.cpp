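#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Single-pass IIR transfer-function filter, direct form II transposed,
// zero initial conditions. Columns of x are filtered independently.
// [[Rcpp::export]]
NumericMatrix cpp_iir(NumericVector b, NumericVector a, NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  const int nb = b.size(), na = a.size();
  const int nw = std::max(nb, na) - 1;
  std::vector<double> bb(nw + 1, 0.0), aa(nw + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  const double a0 = aa[0];
  for (int i = 0; i <= nw; ++i) bb[i] /= a0;
  for (int i = 1; i <= nw; ++i) aa[i] /= a0;
  NumericMatrix y(n, m);
  const double *bp = bb.data(), *ap = aa.data();
  std::vector<double> w(std::max(nw, 1));
  for (int j = 0; j < m; ++j) {
    const double *xp = &x(0, j);
    double *yp = &y(0, j);
    std::fill(w.begin(), w.end(), 0.0);
    double *wp = w.data();
    for (int i = 0; i < n; ++i) {
      const double xi = xp[i];
      const double yi = bp[0] * xi + wp[0];
      for (int k = 0; k < nw - 1; ++k) {
        wp[k] = bp[k + 1] * xi + wp[k + 1] - ap[k + 1] * yi;
      }
      if (nw > 0) wp[nw - 1] = bp[nw] * xi - ap[nw] * yi;
      yp[i] = yi;
    }
  }
  return y;
}
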