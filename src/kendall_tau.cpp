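#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Tie-corrected Kendall tau-b between two aligned numeric buffers of length n.
// Returns NA when either vector is constant (denominator 0).
static double tau_b_pair(const double* x, const double* y, int n) {
  long long conc = 0, disc = 0, tx = 0, ty = 0;
  for (int a = 0; a < n - 1; ++a) {
    for (int b = a + 1; b < n; ++b) {
      const double dx = x[a] - x[b];
      const double dy = y[a] - y[b];
      if (dx == 0.0) ++tx;
      if (dy == 0.0) ++ty;
      if (dx != 0.0 && dy != 0.0) {
        if ((dx > 0.0) == (dy > 0.0)) ++conc; else ++disc;
      }
    }
  }
  const long long n0 = (long long)n * (n - 1) / 2;
  const double den = std::sqrt((double)(n0 - tx)) * std::sqrt((double)(n0 - ty));
  if (den == 0.0) return NA_REAL;
  return (double)(conc - disc) / den;
}

// All-pairs tau-b between rows of X (e.g. lipids x samples) and rows of Y
// (proteins x samples), pairwise-complete over the shared sample axis.
// tau is NA where fewer than min_overlap complete pairs exist or where a
// vector is constant on the complete positions; n_pairs always records the
// complete-pair count.
// [[Rcpp::export]]
List tau_matrix_cpp(NumericMatrix X, NumericMatrix Y, int min_overlap) {
  const int nx = X.nrow(), ny = Y.nrow(), m = X.ncol();
  if (Y.ncol() != m) stop("X and Y must have the same number of columns");
  if (min_overlap < 2) min_overlap = 2;
  NumericMatrix tau(nx, ny);
  IntegerMatrix npairs(nx, ny);
  std::vector<double> xv(m), yv(m);
  // row-major copies so the inner gather is cache-friendly
  std::vector<double> xr((size_t)nx * m), yr((size_t)ny * m);
  for (int i = 0; i < nx; ++i)
    for (int s = 0; s < m; ++s) xr[(size_t)i * m + s] = X(i, s);
  for (int j = 0; j < ny; ++j)
    for (int s = 0; s < m; ++s) yr[(size_t)j * m + s] = Y(j, s);

  for (int i = 0; i < nx; ++i) {
    const double* xi = &xr[(size_t)i * m];
    for (int j = 0; j < ny; ++j) {
      const double* yj = &yr[(size_t)j * m];
      int n = 0;
      for (int s = 0; s < m; ++s) {
        if (R_finite(xi[s]) && R_finite(yj[s])) {
          xv[n] = xi[s];
          yv[n] = yj[s];
          ++n;
        }
      }
      npairs(i, j) = n;
      tau(i, j) = (n < min_overlap) ? NA_REAL : tau_b_pair(xv.data(), yv.data(), n);
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["tau"] = tau, _["n_pairs"] = npairs);
}
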