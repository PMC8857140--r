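#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system.
// dl: sub-diagonal (n-1), d: diagonal (n), du: super-diagonal (n-1), b: rhs.
// The 1D implicit diffusion step solves one of these per species per step,
// which is the hot loop of the moving-domain integrator.
// [[Rcpp::export]]
NumericVector solve_tridiag(NumericVector dl, NumericVector d,
                            NumericVector du, NumericVector b) {
  int n = d.size();
  if (dl.size() != n - 1 || du.size() != n - 1 || b.size() != n)
    stop("inconsistent tridiagonal system dimensions");
  NumericVector cp(n - 1), x(n);
  double den = d[0];
  if (den == 0.0) stop("singular tridiagonal system");
  if (n > 1) cp[0] = du[0] / den;
  x[0] = b[0] / den;
  for (int i = 1; i < n; ++i) {
    den = d[i] - dl[i - 1] * cp[i - 1];
    if (den == 0.0) stop("singular tridiagonal system");
    if (i < n - 1) cp[i] = du[i] / den;
    x[i] = (b[i] - dl[i - 1] * x[i - 1]) / den;
  }
  for (int i = n - 2; i >= 0; --i) x[i] -= cp[i] * x[i + 1];
  return x;
}
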