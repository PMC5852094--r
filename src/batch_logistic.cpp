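// Batch logistic regression for per-SNP outcome scans.
// One IRLS fit per SNP column appended to a fixed covariate design.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Returns an m x 3 matrix: beta_snp, se_snp, converged (1/0).
// [[Rcpp::export]]
Rcpp::NumericMatrix batch_logistic(const arma::mat& covars,
                                   const arma::vec& y,
                                   const arma::mat& snps,
                                   double tol, int maxit) {
  const uword n = covars.n_rows, q = covars.n_cols, m = snps.n_cols;
  if (y.n_elem != n || snps.n_rows != n)
    Rcpp::stop("dimension mismatch in batch_logistic");
  Rcpp::NumericMatrix out(m, 3);
  mat X(n, q + 1);
  X.cols(0, q - 1) = covars;

  for (uword j = 0; j < m; ++j) {
    X.col(q) = snps.col(j);
    vec beta(q + 1, fill::zeros);
    bool conv = false, ok = true;
    double dev_old = datum::inf;
    for (int it = 0; it < maxit; ++it) {
      vec eta = X * beta;
      eta = clamp(eta, -30.0, 30.0);
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec w = mu % (1.0 - mu);
      w = clamp(w, 1e-10, 0.25);
      vec z = eta + (y - mu) / w;
      mat Xw = X.each_col() % sqrt(w);
      vec zw = z % sqrt(w);
      vec beta_new;
      if (!solve(beta_new, Xw.t() * Xw, Xw.t() * zw, solve_opts::no_approx)) {
        ok = false;
        break;
      }
      beta = beta_new;
      if (!beta.is_finite()) { ok = false; break; }
      // glm-style relative deviance convergence
      vec eta2 = clamp(X * beta, -30.0, 30.0);
      vec mu2 = 1.0 / (1.0 + exp(-eta2));
      mu2 = clamp(mu2, 1e-12, 1.0 - 1e-12);
      double dev = -2.0 * accu(y % log(mu2) + (1.0 - y) % log(1.0 - mu2));
      if (std::abs(dev - dev_old) / (std::abs(dev) + 0.1) < tol) {
        conv = true;
        break;
      }
      dev_old = dev;
    }
    double se = NA_REAL;
    if (ok) {
      vec eta = clamp(X * beta, -30.0, 30.0);
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec w = mu % (1.0 - mu);
      mat info = X.t() * (X.each_col() % w);
      mat cov;
      if (inv_sympd(cov, info))
        se = std::sqrt(cov(q, q));
      else
        ok = false;
    }
    out(j, 0) = ok ? beta(q) : NA_REAL;
    out(j, 1) = se;
    out(j, 2) = (ok && conv) ? 1.0 : 0.0;
  }
  return out;
}
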