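#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Block-coordinate graphical lasso with an entrywise penalty matrix.
//
// Solves  min_Omega  -logdet(Omega) + tr(Omega S) + sum_ij Lambda_ij |Omega_ij|
// where off-diagonal entries with Lambda_ij = Inf are constrained to exactly
// zero.  One column/row at a time: the working covariance W has its diagonal
// fixed at diag(S) + diag(Lambda); the off-diagonal part of each column is
// obtained from a lasso regression on the free entries (coordinate descent),
// following the covariance-update formulation of the graphical lasso.
//
// Warm starts: pass W and B (matrix of per-column regression coefficients)
// from a previous solve; otherwise W = S + diag(Lambda), B = 0.
// [[Rcpp::export]]
Rcpp::List pglasso_cpp(const arma::mat& S, const arma::mat& Lambda,
                       arma::mat W, arma::mat B,
                       double tol, int maxit, double inner_tol, int inner_maxit) {
  const uword p = S.n_rows;
  vec ldiag(p);
  for (uword j = 0; j < p; ++j) ldiag(j) = Lambda(j, j);

  // free off-diagonal entries per column
  std::vector<uvec> free_idx(p);
  for (uword j = 0; j < p; ++j) {
    std::vector<uword> v;
    for (uword i = 0; i < p; ++i)
      if (i != j && std::isfinite(Lambda(i, j))) v.push_back(i);
    free_idx[j] = uvec(v);
  }

  // enforce the fixed diagonal
  for (uword j = 0; j < p; ++j) W(j, j) = S(j, j) + ldiag(j);

  bool converged = false;
  int it = 0;
  for (; it < maxit; ++it) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      const uvec& idx = free_idx[j];
      vec w_new(p, fill::zeros);
      if (idx.n_elem > 0) {
        const uword m = idx.n_elem;
        const mat W11 = W.submat(idx, idx);
        vec b = B.col(j);
        b = b.elem(idx);
        vec s12(m), lam(m);
        for (uword a = 0; a < m; ++a) {
          s12(a) = S(idx(a), j);
          lam(a) = Lambda(idx(a), j);
        }
        // residual r = s12 - W11 b, maintained across coordinate updates
        vec r = s12 - W11 * b;
        for (int in_it = 0; in_it < inner_maxit; ++in_it) {
          double d_in = 0.0;
          for (uword a = 0; a < m; ++a) {
            const double rj = r(a) + W11(a, a) * b(a);
            double bi = 0.0;
            if (rj > lam(a)) bi = (rj - lam(a)) / W11(a, a);
            else if (rj < -lam(a)) bi = (rj + lam(a)) / W11(a, a);
            const double db = bi - b(a);
            if (db != 0.0) {
              r -= db * W11.col(a);
              b(a) = bi;
              const double ad = std::fabs(db);
              if (ad > d_in) d_in = ad;
            }
          }
          if (d_in < inner_tol) break;
        }
        vec bfull(p, fill::zeros);
        bfull.elem(idx) = b;
        B.col(j) = bfull;
        // w12 = W[-j,-j] * beta ; only columns in idx contribute
        for (uword a = 0; a < m; ++a)
          if (b(a) != 0.0) w_new += W.col(idx(a)) * b(a);
        w_new(j) = 0.0;  // handled by fixed diagonal
      } else {
        B.col(j).zeros();
      }
      for (uword i = 0; i < p; ++i) {
        if (i == j) continue;
        double diff = std::fabs(W(i, j) - w_new(i));
        if (diff > max_delta) max_delta = diff;
        W(i, j) = w_new(i);
        W(j, i) = w_new(i);
      }
    }
    if (max_delta < tol) { converged = true; ++it; break; }
  }

  // recover Omega from the final regression coefficients
  mat Omega(p, p, fill::zeros);
  bool pd_ok = true;
  for (uword j = 0; j < p; ++j) {
    const vec beta = B.col(j);
    double denom = W(j, j) - dot(W.col(j), beta);  // beta(j) == 0
    if (denom <= 0) { pd_ok = false; denom = datum::eps; }
    const double theta = 1.0 / denom;
    Omega(j, j) = theta;
    const uvec& idx = free_idx[j];
    for (uword a = 0; a < idx.n_elem; ++a)
      Omega(idx(a), j) = -beta(idx(a)) * theta;
  }
  // symmetrize; keep exact zeros where both directions vanished
  mat Osym = 0.5 * (Omega + Omega.t());
  return Rcpp::List::create(
      Rcpp::Named("Omega") = Osym,
      Rcpp::Named("W") = W,
      Rcpp::Named("B") = B,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("pd") = pd_ok);
}
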