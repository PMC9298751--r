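// Iteratively reweighted least squares for binomial-logit GLMs.
// Kept deliberately minimal: dense design, no offset/weights, ridge fuzz on
// the normal equations only when the solve fails (separation-prone resamples).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::vec irls_logistic_cpp(const arma::mat& X, const arma::vec& y,
                            int maxit = 30, double tol = 1e-8) {
  vec beta(X.n_cols, fill::zeros);
  for (int it = 0; it < maxit; ++it) {
    vec eta = X * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    vec z = eta + (y - mu) / w;
    mat Xw = X.each_col() % w;
    mat XtWX = X.t() * Xw;
    vec XtWz = Xw.t() * z;
    vec beta_new;
    bool ok = solve(beta_new, XtWX, XtWz, solve_opts::no_approx);
    if (!ok) {
      XtWX.diag() += 1e-8;
      beta_new = solve(XtWX, XtWz);
    }
    double delta = max(abs(beta_new - beta));
    beta = beta_new;
    if (delta < tol) break;
  }
  return beta;
}
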