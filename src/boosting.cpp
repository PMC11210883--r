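#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Joint componentwise L2 boosting over all response columns.
//
// Xs: n x p design with columns already centered/scaled; excluded (constant)
//     columns are flagged by ss == 0.
// Yc: n x J centered responses.
// ss: per-column sum of squares of Xs (0 => never selected).
//
// Per iteration and response j: pick the column maximizing the squared-error
// reduction (C_pj^2 / ss_p with C = Xs' R), move learning_rate times its
// least-squares coefficient, update the residual. Returns the p x J
// coefficient matrix accumulated on the standardized scale.
// [[Rcpp::export]]
arma::mat boost_fit_cpp(const arma::mat& Xs, const arma::mat& Yc,
                        const int n_iter, const double lr,
                        const arma::vec& ss) {
  const uword p = Xs.n_cols, J = Yc.n_cols;
  mat R = Yc;
  mat coef(p, J, fill::zeros);
  vec inv_ss(p, fill::zeros);
  for (uword c = 0; c < p; ++c)
    if (ss(c) > 0) inv_ss(c) = 1.0 / ss(c);
  for (int it = 0; it < n_iter; ++it) {
    mat C = Xs.t() * R;                      // p x J inner products
    mat score = square(C);
    score.each_col() %= inv_ss;              // SSE reduction per (col, response)
    for (uword j = 0; j < J; ++j) {
      uword sel;
      double best = score.col(j).max(sel);
      if (!(best > 0)) continue;             // all-zero residual correlation
      double beta = lr * C(sel, j) * inv_ss(sel);
      coef(sel, j) += beta;
      R.col(j) -= beta * Xs.col(sel);
    }
  }
  return coef;
}
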