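#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set NNLS expressed on the normal equations:
// minimise ||Z x - d||^2 s.t. x >= 0, given G = Z'Z and f = Z'd.
static vec nnls_gram_one(const mat& G, const vec& f, double tol) {
  const uword K = G.n_rows;
  vec x(K, fill::zeros);
  uvec passive(K, fill::zeros);   // 1 = in passive (free) set
  vec w = f;                      // gradient  f - G x  (x = 0)

  for (uword outer = 0; outer < 30 * K + 30; ++outer) {
    // most-violating free variable
    double wmax = -datum::inf;
    sword jmax = -1;
    for (uword j = 0; j < K; ++j) {
      if (!passive(j) && w(j) > wmax) { wmax = w(j); jmax = j; }
    }
    if (jmax < 0 || wmax <= tol) break;
    passive(jmax) = 1;

    for (uword inner = 0; inner < 30 * K + 30; ++inner) {
      uvec P = find(passive == 1);
      vec s_p;
      bool ok = solve(s_p, G.submat(P, P), f.elem(P),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) s_p = pinv(G.submat(P, P)) * f.elem(P);

      if (s_p.min() > 0) {
        x.zeros();
        x.elem(P) = s_p;
        break;
      }
      // step toward s, dropping the first variable that hits zero
      double alpha = datum::inf;
      for (uword i = 0; i < P.n_elem; ++i) {
        if (s_p(i) <= 0) {
          double a = x(P(i)) / (x(P(i)) - s_p(i));
          if (a < alpha) alpha = a;
        }
      }
      for (uword i = 0; i < P.n_elem; ++i)
        x(P(i)) += alpha * (s_p(i) - x(P(i)));
      for (uword i = 0; i < P.n_elem; ++i)
        if (x(P(i)) <= tol) { passive(P(i)) = 0; x(P(i)) = 0; }
    }
    w = f - G * x;
  }
  return x;
}

//' @title Row-wise non-negative least squares from Gram matrices
//' @description Solves, for every row i of \code{F}, the problem
//'   min ||Z x - d_i|| s.t. x >= 0 where \code{G} = Z'Z and \code{F[i,]} = Z'd_i.
//'   Used as the mode-update kernel of the non-negative PARAFAC ALS sweeps.
//' @param G K x K Gram matrix (symmetric positive semi-definite).
//' @param F m x K matrix of right-hand sides (one row per least-squares problem).
//' @return m x K matrix of non-negative solutions.
//' @keywords internal
// [[Rcpp::export]]
arma::mat nnls_gram_rows(const arma::mat& G, const arma::mat& F) {
  const uword m = F.n_rows;
  mat X(m, G.n_rows);
  double tol = 1e-12 * std::max(1.0, G.diag().max());
  for (uword i = 0; i < m; ++i)
    X.row(i) = nnls_gram_one(G, F.row(i).t(), tol).t();
  return X;
}
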