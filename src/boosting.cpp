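#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Greedy L2 boosting of a single response channel with validation-based
// early stopping.
//
// G  = X_tr' X_tr (Gram matrix of the training design)
// c  = X_tr' y_tr
// Xv = validation design, yv = validation response
// delta = coefficient increment, patience = consecutive non-improving steps
// tolerated before stopping. Ties among candidate steps are broken by the
// lowest column index (arma::index_max returns the first maximum).
// Returns the coefficient vector at the best validation error.
// [[Rcpp::export]]
Rcpp::List boost_channel_cpp(const arma::mat& G, const arma::vec& c,
                             const arma::mat& Xv, const arma::vec& yv,
                             double delta, int patience, int max_steps) {
  const uword p = G.n_rows;
  vec beta(p, fill::zeros), best_beta(p, fill::zeros);
  vec rdot = c;                       // X_tr' (y_tr - X_tr beta)
  vec pred_v(yv.n_elem, fill::zeros);
  vec gdiag = G.diag();
  double best_verr = dot(yv, yv);     // validation error at beta = 0
  int since = 0, steps = 0;
  for (steps = 0; steps < max_steps; ++steps) {
    vec red = 2.0 * delta * abs(rdot) - delta * delta * gdiag;
    uword j = red.index_max();
    if (!(red(j) > 0)) break;         // no step reduces training error
    double s = (rdot(j) > 0) ? 1.0 : -1.0;
    beta(j) += s * delta;
    rdot -= (s * delta) * G.col(j);
    pred_v += (s * delta) * Xv.col(j);
    double verr = accu(square(yv - pred_v));
    if (verr < best_verr) {
      best_verr = verr;
      best_beta = beta;
      since = 0;
    } else if (++since >= patience) {
      ++steps;
      break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = best_beta,
                            Rcpp::Named("steps") = steps,
                            Rcpp::Named("val_error") = best_verr);
}
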