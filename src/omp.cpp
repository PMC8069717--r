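#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Orthogonal matching pursuit over the columns of Y.
// Greedy selection of the atom with maximal |correlation| with the current
// residual (ties -> lowest atom index), least-squares refit on the support
// after every selection, stopping at T0 atoms or residual norm <= tol.
// [[Rcpp::export]]
Rcpp::List omp_encode_cpp(const arma::mat& D, const arma::mat& Y,
                          const int T0, const double tol) {
  const arma::uword M = D.n_cols, nsig = Y.n_cols;
  arma::mat A(M, nsig, arma::fill::zeros);
  arma::vec rnorm(nsig, arma::fill::zeros);
  for (arma::uword s = 0; s < nsig; ++s) {
    const arma::vec y = Y.col(s);
    arma::vec r = y;
    double rn = arma::norm(r);
    const double corr_floor = 1e-12 * std::max(1.0, arma::norm(y));
    std::vector<arma::uword> supp;
    std::vector<bool> used(M, false);
    arma::vec coef;
    while ((int)supp.size() < T0 && rn > tol) {
      const arma::vec c = D.t() * r;
      int best = -1;
      double bv = 0.0;
      for (arma::uword k = 0; k < M; ++k) {
        if (used[k]) continue;
        const double v = std::abs(c[k]);
        if (v > bv) { bv = v; best = (int)k; }
      }
      if (best < 0 || bv <= corr_floor) break;
      used[best] = true;
      supp.push_back((arma::uword)best);
      arma::uvec si(supp.size());
      for (size_t t = 0; t < supp.size(); ++t) si[t] = supp[t];
      const arma::mat Ds = D.cols(si);
      coef = arma::solve(Ds, y);
      r = y - Ds * coef;
      rn = arma::norm(r);
    }
    for (size_t t = 0; t < supp.size(); ++t) A(supp[t], s) = coef[t];
    rnorm[s] = rn;
  }
  return Rcpp::List::create(Rcpp::_["alpha"] = A,
                            Rcpp::_["residual_norm"] = rnorm);
}
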