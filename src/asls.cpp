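#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Solve A z = rhs where A is symmetric positive definite and
// pentadiagonal, given by its diagonal d0, first subdiagonal d1
// (A(i+1,i)) and second subdiagonal d2 (A(i+2,i)).  Banded LDL'
// factorization, O(n).
static void penta_solve(const std::vector<double>& d0,
                        const std::vector<double>& d1,
                        const std::vector<double>& d2,
                        const std::vector<double>& rhs,
                        std::vector<double>& z) {
  int n = (int)d0.size();
  std::vector<double> l1(n, 0.0), l2(n, 0.0), D(n, 0.0), y(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double di = d0[i];
    if (i >= 1) di -= l1[i] * l1[i] * D[i - 1];
    if (i >= 2) di -= l2[i] * l2[i] * D[i - 2];
    D[i] = di;
    if (i + 1 < n) {
      // L(i+1,i) = (A(i+1,i) - L(i+1,i-1) D(i-1) L(i,i-1)) / D(i)
      double e = d1[i];
      if (i >= 1) e -= l2[i + 1] * D[i - 1] * l1[i];
      l1[i + 1] = e / D[i];
    }
    if (i + 2 < n) l2[i + 2] = d2[i] / D[i];
  }
  for (int i = 0; i < n; ++i) {               // L y = rhs
    double v = rhs[i];
    if (i >= 1) v -= l1[i] * y[i - 1];
    if (i >= 2) v -= l2[i] * y[i - 2];
    y[i] = v;
  }
  for (int i = n - 1; i >= 0; --i) {          // L' z = D^{-1} y
    double v = y[i] / D[i];
    if (i + 1 < n) v -= l1[i + 1] * z[i + 1];
    if (i + 2 < n) v -= l2[i + 2] * z[i + 2];
    z[i] = v;
  }
}

// Asymmetric least squares baseline (Eilers-style): minimize
// sum_i w_i (y_i - z_i)^2 + lambda * sum (d2 z)^2 with w_i = p where
// y_i > z_i and 1-p otherwise, iterated until the weights stabilize.
// The weight update depends only on the sign of the residual, so the
// estimate is exactly equivariant under positive rescaling of y.
static void asls_one(const double* yv, int n, double lambda, double p,
                     int max_iter, double* zout) {
  // bands of lambda * D2'D2, D2 the (n-2) x n second-difference operator
  std::vector<double> base0(n, 0.0), base1(n, 0.0), base2(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int jlo = std::max(0, i - 2), jhi = std::min(n - 3, i);
    double s = 0.0;
    for (int j = jlo; j <= jhi; ++j) {
      double c = (i - j == 1) ? -2.0 : 1.0;
      s += c * c;
    }
    base0[i] = lambda * s;
  }
  for (int i = 0; i + 1 < n; ++i) {
    int jlo = std::max(0, i - 1), jhi = std::min(n - 3, i);
    double s = 0.0;
    for (int j = jlo; j <= jhi; ++j) {
      double c1 = (i - j == 1) ? -2.0 : 1.0;
      double c2 = (i + 1 - j == 1) ? -2.0 : 1.0;
      s += c1 * c2;
    }
    base1[i] = lambda * s;
  }
  for (int i = 0; i + 2 < n; ++i) base2[i] = lambda;  // single row j = i
  std::vector<double> w(n, 1.0), d0(n), rhs(n), z(n, 0.0);
  for (int it = 0; it < max_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      d0[i] = base0[i] + w[i];
      rhs[i] = w[i] * yv[i];
    }
    penta_solve(d0, base1, base2, rhs, z);
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      double nw = (yv[i] > z[i]) ? p : (1.0 - p);
      if (nw != w[i]) changed = true;
      w[i] = nw;
    }
    if (!changed && it > 0) break;
  }
  for (int i = 0; i < n; ++i) zout[i] = z[i];
}

// [[Rcpp::export(name = ".aslsBaselineCpp")]]
NumericVector asls_baseline(NumericVector y, double lambda, double p,
                            int max_iter) {
  int n = y.size();
  NumericVector z(n);
  asls_one(REAL(y), n, lambda, p, max_iter, REAL(z));
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(z[i])) stop("AsLS baseline diverged");
  return z;
}

// [[Rcpp::export(name = ".aslsBaselineMatCpp")]]
NumericMatrix asls_baseline_mat(NumericMatrix Y, double lambda, double p,
                                int max_iter) {
  // Y: pixels x channels; returns the per-pixel baselines, same shape
  int np = Y.nrow(), n = Y.ncol();
  NumericMatrix Z(np, n);
  std::vector<double> yv(n), zv(n);
  for (int px = 0; px < np; ++px) {
    for (int j = 0; j < n; ++j) yv[j] = Y(px, j);
    asls_one(yv.data(), n, lambda, p, max_iter, zv.data());
    for (int j = 0; j < n; ++j) {
      if (!std::isfinite(zv[j]))
        stop("AsLS baseline diverged at pixel %d", px + 1);
      Z(px, j) = zv[j];
    }
  }
  return Z;
}

// [[Rcpp::export(name = ".colMedianCpp")]]
NumericVector col_median(NumericMatrix X) {
  int nr = X.nrow(), nc = X.ncol();
  NumericVector out(nc);
  std::vector<double> v(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) v[i] = X(i, j);
    std::sort(v.begin(), v.end());
    out[j] = (nr % 2) ? v[nr / 2] : 0.5 * (v[nr / 2 - 1] + v[nr / 2]);
  }
  return out;
}
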