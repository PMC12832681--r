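#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the weighted Lasso
//   min_b  1/2 * ||yc - Xc b||^2 + lam * sum_j w_j |b_j|
// over a decreasing lambda path with warm starts. Xc and yc arrive
// centered (and optionally scaled) from R; the intercept is handled
// there. colss holds the column sums of squares of Xc.
// [[Rcpp::export(name = ".cd_lasso_path")]]
List cd_lasso_path(const NumericMatrix& Xc,
                   const NumericVector& yc,
                   const NumericVector& w,
                   const NumericVector& lambdas,
                   const NumericVector& colss,
                   double tol,
                   int max_iter) {
  const int n = Xc.nrow(), p = Xc.ncol(), nl = lambdas.size();
  NumericMatrix beta(p, nl);
  IntegerVector n_iter(nl);
  LogicalVector converged(nl);

  std::vector<double> b(p, 0.0), r(yc.begin(), yc.end());

  for (int li = 0; li < nl; ++li) {
    const double lam = lambdas[li];
    bool ok = false;
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
      double max_change = 0.0;
      for (int j = 0; j < p; ++j) {
        const double ss = colss[j];
        if (ss <= 0.0) { b[j] = 0.0; continue; }
        const double* xj = &Xc(0, j);
        double rho = 0.0;
        for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
        rho += ss * b[j];
        const double thr = lam * w[j];
        double bn;
        if (rho > thr)       bn = (rho - thr) / ss;
        else if (rho < -thr) bn = (rho + thr) / ss;
        else                 bn = 0.0;
        const double d = bn - b[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
          b[j] = bn;
          const double ad = std::fabs(d);
          if (ad > max_change) max_change = ad;
        }
      }
      if (max_change < tol) { ok = true; ++it; break; }
    }
    for (int j = 0; j < p; ++j) beta(j, li) = b[j];
    n_iter[li] = it;
    converged[li] = ok;
  }
  return List::create(_["beta"] = beta, _["n_iter"] = n_iter,
                      _["converged"] = converged);
}
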