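#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the lasso on Gram-matrix sufficient
// statistics, warm-started along a decreasing penalty grid.
// Solves min_beta 1/(2n)||y - b0 - X beta||^2 + lambda ||beta||_1 with X
// standardized; gram = X'X/n, xty = X'(y - mean(y))/n.
// [[Rcpp::export(name = ".cd_lasso_path")]]
NumericMatrix cd_lasso_path(NumericMatrix gram, NumericVector xty,
                            NumericVector lambda, double tol, int max_iter) {
  const int p = gram.nrow();
  const int nl = lambda.size();
  NumericMatrix out(p, nl);
  std::vector<double> beta(p, 0.0);
  std::vector<double> g(p);          // gram %*% beta, maintained incrementally
  std::fill(g.begin(), g.end(), 0.0);

  for (int li = 0; li < nl; ++li) {
    const double lam = lambda[li];
    for (int it = 0; it < max_iter; ++it) {
      double delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double old = beta[j];
        const double djj = gram(j, j);
        if (djj <= 0.0) continue;
        const double z = xty[j] - g[j] + djj * old;
        double bj = 0.0;
        if (z > lam) bj = (z - lam) / djj;
        else if (z < -lam) bj = (z + lam) / djj;
        if (bj != old) {
          const double diff = bj - old;
          beta[j] = bj;
          for (int k = 0; k < p; ++k) g[k] += gram(k, j) * diff;
          const double ad = std::fabs(diff);
          if (ad > delta) delta = ad;
        }
      }
      if (delta < tol) break;
    }
    for (int j = 0; j < p; ++j) out(j, li) = beta[j];
  }
  return out;
}
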