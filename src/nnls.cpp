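// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Lawson-Hanson active-set non-negative least squares for one spectrum.
// S: B x F design (library endmembers in columns), y: length-B observation.
// Returns coefficients (length F) minimising ||S x - y||_2 subject to x >= 0.
static vec nnls_one(const mat& S, const vec& y, double tol, int max_iter) {
  const uword F = S.n_cols;
  vec x(F, fill::zeros);
  std::vector<bool> passive(F, false);
  vec w = S.t() * (y - S * x);          // gradient of -0.5*RSS
  int iter = 0;
  while (iter++ < max_iter) {
    // find most violating zero-constrained variable
    sword t = -1;
    double wmax = tol;
    for (uword j = 0; j < F; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (sword)j; }
    if (t < 0) break;                    // KKT satisfied
    passive[(uword)t] = true;
    // inner loop: solve on the passive set, retreat while infeasible
    for (;;) {
      uvec P(F);
      uword np = 0;
      for (uword j = 0; j < F; ++j) if (passive[j]) P(np++) = j;
      P = P.head(np);
      vec z;
      bool ok = solve(z, S.cols(P), y, solve_opts::fast);
      if (!ok) z = pinv(S.cols(P)) * y;
      if (z.min() > tol) {
        x.zeros();
        x(P) = z;
        break;
      }
      // step toward z until the first passive variable hits zero
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k)
        if (z(k) <= tol) {
          double a = x(P(k)) / (x(P(k)) - z(k));
          if (a < alpha) alpha = a;
        }
      for (uword k = 0; k < np; ++k)
        x(P(k)) += alpha * (z(k) - x(P(k)));
      for (uword k = 0; k < np; ++k)
        if (x(P(k)) <= tol) { passive[P(k)] = false; x(P(k)) = 0.0; }
    }
    w = S.t() * (y - S * x);
  }
  return x;
}

// [[Rcpp::export(name = ".nnls_batch_cpp")]]
Rcpp::List nnls_batch_cpp(const arma::mat& S, const arma::mat& Y,
                          double tol = 1e-10, int max_iter = 200) {
  // Y: N x B (one spectrum per row). Fast path: unconstrained least squares
  // for all rows at once; rows with any negative coefficient fall back to
  // the per-row active-set solver.
  const uword N = Y.n_rows, F = S.n_cols;
  mat pinvS = pinv(S);                  // F x B
  mat X = Y * pinvS.t();                // N x F unconstrained solution
  vec resid(N);
  for (uword i = 0; i < N; ++i) {
    bool neg = false;
    for (uword j = 0; j < F; ++j) if (X(i, j) < -tol) { neg = true; break; }
    if (neg) {
      vec x = nnls_one(S, Y.row(i).t(), tol, max_iter);
      X.row(i) = x.t();
    } else {
      for (uword j = 0; j < F; ++j) if (X(i, j) < 0) X(i, j) = 0;
    }
    resid(i) = norm(Y.row(i).t() - S * X.row(i).t(), 2);
  }
  return Rcpp::List::create(Rcpp::Named("coef") = X,
                            Rcpp::Named("resid") = resid);
}
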