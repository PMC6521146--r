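#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pathwise coordinate descent for the lasso
//
//   minimise (1/2n) * ||y - X b||^2 + lambda * sum_j |b_j|
//
// over a decreasing lambda grid with warm starts. X is expected column-centred
// (an unpenalised intercept is handled by centring in the R wrapper); xvar
// holds (1/n) x_j' x_j. Columns with xvar <= 0 are frozen at zero.
static inline double soft_threshold(double rho, double lam) {
  if (rho > lam) return rho - lam;
  if (rho < -lam) return rho + lam;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_lasso_path")]]
NumericMatrix cd_lasso_path(const NumericMatrix& X, const NumericVector& y,
                            const NumericVector& lambda, const NumericVector& xvar,
                            double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix beta(p, L);
  std::vector<double> b(p, 0.0);
  std::vector<double> r(y.begin(), y.end());

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    // one full sweep, then iterate on the active set until stable,
    // then re-check the full set (glmnet-style strategy)
    bool converged_full = false;
    int it = 0;
    while (!converged_full && it < maxit) {
      // full sweep
      double maxd = 0.0;
      for (int j = 0; j < p; ++j) {
        if (xvar[j] <= 0.0) continue;
        const double* xj = &X(0, j);
        double xr = 0.0;
        for (int i = 0; i < n; ++i) xr += xj[i] * r[i];
        const double rho = xr / n + xvar[j] * b[j];
        const double bj = soft_threshold(rho, lam) / xvar[j];
        const double d = b[j] - bj;
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] += xj[i] * d;
          b[j] = bj;
          const double ad = std::fabs(d);
          if (ad > maxd) maxd = ad;
        }
      }
      ++it;
      if (maxd < tol) { converged_full = true; break; }
      // inner iterations restricted to the current active set
      while (it < maxit) {
        double maxd_in = 0.0;
        for (int j = 0; j < p; ++j) {
          if (xvar[j] <= 0.0 || b[j] == 0.0) continue;
          const double* xj = &X(0, j);
          double xr = 0.0;
          for (int i = 0; i < n; ++i) xr += xj[i] * r[i];
          const double rho = xr / n + xvar[j] * b[j];
          const double bj = soft_threshold(rho, lam) / xvar[j];
          const double d = b[j] - bj;
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) r[i] += xj[i] * d;
            b[j] = bj;
            const double ad = std::fabs(d);
            if (ad > maxd_in) maxd_in = ad;
          }
        }
        ++it;
        if (maxd_in < tol) break;
      }
    }
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return beta;
}

// Leave-one-regulator-out loss increments for one tumor.
//
// For residuals r of the fitted model and feature columns x_j with
// coefficients w_j, zeroing w_j changes the squared loss by
//   sum_g (r_g + w_j x_gj)^2 - r_g^2 = 2 w_j (x_j' r) + w_j^2 (x_j' x_j).
// Returns the per-feature increment vector.
// [[Rcpp::export(name = ".loo_loss_increments")]]
NumericVector loo_loss_increments(const NumericMatrix& X, const NumericVector& resid,
                                  const NumericVector& w) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector out(p);
  for (int j = 0; j < p; ++j) {
    const double wj = w[j];
    if (wj == 0.0) { out[j] = 0.0; continue; }
    const double* xj = &X(0, j);
    double xr = 0.0, xx = 0.0;
    for (int i = 0; i < n; ++i) { xr += xj[i] * resid[i]; xx += xj[i] * xj[i]; }
    out[j] = 2.0 * wj * xr + wj * wj * xx;
  }
  return out;
}
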