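#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the unscaled Lasso objective
//   || y - X w ||_2^2 + lambda * || w ||_1
// (no 1/(2N) factor). Update for column j with c_j = ||x_j||^2:
//   w_j <- S(x_j' r_j, lambda / 2) / c_j
// where r_j is the partial residual excluding column j and S is the
// soft-threshold operator. Convergence on max absolute coefficient change.

static inline double softThreshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static inline double cdSweep(const NumericMatrix& X, double g,
                             std::vector<double>& w, std::vector<double>& r,
                             const std::vector<double>& colss,
                             const std::vector<int>& idx) {
  const int n = X.nrow();
  double maxDelta = 0.0;
  for (size_t jj = 0; jj < idx.size(); ++jj) {
    const int j = idx[jj];
    if (colss[j] <= 0.0) continue;
    const double* xj = &X(0, j);
    double rho = 0.0;
    for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
    rho += colss[j] * w[j];
    double wNew = softThreshold(rho, g) / colss[j];
    double delta = wNew - w[j];
    if (delta != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= delta * xj[i];
      w[j] = wNew;
      double ad = std::fabs(delta);
      if (ad > maxDelta) maxDelta = ad;
    }
  }
  return maxDelta;
}

// Full sweeps alternating with active-set sweeps (the usual coordinate
// descent acceleration): converge on the nonzero set, then one full sweep;
// stop when the full sweep itself moves nothing beyond tol.
static void cdSolve(const NumericMatrix& X, double lambda, double tol,
                    int maxit, std::vector<double>& w, std::vector<double>& r,
                    const std::vector<double>& colss) {
  const int q = X.ncol();
  const double g = lambda / 2.0;
  std::vector<int> all(q);
  for (int j = 0; j < q; ++j) all[j] = j;
  int used = 0;
  while (used < maxit) {
    double d = cdSweep(X, g, w, r, colss, all);
    ++used;
    if (d < tol) break;
    std::vector<int> active;
    active.reserve(q);
    for (int j = 0; j < q; ++j) if (w[j] != 0.0) active.push_back(j);
    while (used < maxit) {
      double da = cdSweep(X, g, w, r, colss, active);
      ++used;
      if (da < tol) break;
    }
  }
}

// [[Rcpp::export(name = ".lassoSolveC")]]
NumericVector lassoSolveC(NumericMatrix X, NumericVector y, double lambda,
                          double tol = 1e-8, int maxit = 100000,
                          Nullable<NumericVector> wInit = R_NilValue) {
  const int n = X.nrow(), q = X.ncol();
  std::vector<double> w(q, 0.0), r(y.begin(), y.end());
  std::vector<double> colss(q);
  for (int j = 0; j < q; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    colss[j] = s;
  }
  if (wInit.isNotNull()) {
    NumericVector w0(wInit);
    for (int j = 0; j < q; ++j) {
      w[j] = w0[j];
      if (w[j] != 0.0)
        for (int i = 0; i < n; ++i) r[i] -= w[j] * X(i, j);
    }
  }
  cdSolve(X, lambda, tol, maxit, w, r, colss);
  return NumericVector(w.begin(), w.end());
}

// Warm-started path over a decreasing lambda sequence; returns q x L matrix.
// [[Rcpp::export(name = ".lassoPathC")]]
NumericMatrix lassoPathC(NumericMatrix X, NumericVector y,
                         NumericVector lambdas, double tol = 1e-8,
                         int maxit = 100000) {
  const int n = X.nrow(), q = X.ncol(), L = lambdas.size();
  NumericMatrix out(q, L);
  std::vector<double> w(q, 0.0), r(y.begin(), y.end());
  std::vector<double> colss(q);
  for (int j = 0; j < q; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    colss[j] = s;
  }
  for (int l = 0; l < L; ++l) {
    cdSolve(X, lambdas[l], tol, maxit, w, r, colss);
    for (int j = 0; j < q; ++j) out(j, l) = w[j];
  }
  return out;
}
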