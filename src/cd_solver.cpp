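#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Cyclic coordinate descent for the compressed elastic net
//   min_W ||vec(B) - (P ⊗ G) vec(W)||^2 + lambda2 ||W||_2^2 + lambda1 ||W||_1
// expressed through the Gram blocks C = G'G (Q x Q), R = P'P (S x S) and
// the linear term Tm = G'BP (Q x S). Within a column s the gradient
// component (C W R)[, s] is maintained incrementally at O(Q) per update.
// [[Rcpp::export(name = ".cd_elastic_net")]]
Rcpp::List cd_elastic_net(const arma::mat& C, const arma::mat& R,
                          const arma::mat& Tm, const arma::mat& den,
                          arma::mat W, double lambda1, double tol,
                          int max_iter) {
  const uword Q = Tm.n_rows, S = Tm.n_cols;
  const vec dC = C.diag();
  const vec dR = R.diag();
  const double thr = lambda1 / 2.0;
  bool converged = false;
  int it = 0;
  for (int sweep = 1; sweep <= max_iter; ++sweep) {
    it = sweep;
    double max_delta = 0.0;
    for (uword s = 0; s < S; ++s) {
      vec f = C * (W * R.col(s));   // (C W R)[, s]
      const double rss = dR(s);
      for (uword q = 0; q < Q; ++q) {
        const double w_old = W(q, s);
        double z = Tm(q, s) - (f(q) - dC(q) * rss * w_old);
        z = (z > thr) ? (z - thr) : ((z < -thr) ? (z + thr) : 0.0);
        const double w_new = z / den(q, s);
        const double delta = w_new - w_old;
        if (delta != 0.0) {
          W(q, s) = w_new;
          f += (delta * rss) * C.col(q);
          const double ad = std::fabs(delta);
          if (ad > max_delta) max_delta = ad;
        }
      }
    }
    const double wmax = std::max(std::fabs(W.max()), std::fabs(W.min()));
    if (max_delta < tol * (1.0 + wmax)) {
      converged = true;
      break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = converged);
}
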