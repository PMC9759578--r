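#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Block coordinate-descent graphical LASSO (Friedman-style), off-diagonal
// penalty only. Returns the precision matrix Theta, the working covariance
// W = Theta^{-1}, and convergence diagnostics. Warm-started inner lasso
// solved by cyclic coordinate descent.
// [[Rcpp::export(name = ".glassoCd")]]
Rcpp::List glasso_cd(const arma::mat& S, double rho, double tol = 1e-8,
                     int maxit = 200, double innerTol = 1e-10,
                     int innerMaxit = 2000) {
  const int p = S.n_rows;
  mat W = S;                       // diagonal unpenalized: W_ii = S_ii
  mat B(p - 1, p, fill::zeros);    // per-column lasso coefficients
  double offScale = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) offScale += std::fabs(S(i, j));
  offScale /= std::max(1, p * (p - 1));
  double thr = tol * std::max(offScale, 1e-12);

  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    double meanChange = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx(p - 1);
      int k = 0;
      for (int i = 0; i < p; ++i) if (i != j) idx[k++] = i;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      vec s12m = s12.elem(idx);
      vec beta = B.col(j);
      // minimize 0.5 b' W11 b - s12' b + rho ||b||_1
      for (int sweep = 0; sweep < innerMaxit; ++sweep) {
        double del = 0.0;
        for (int m = 0; m < p - 1; ++m) {
          double old = beta[m];
          double g = s12m[m] - dot(W11.col(m), beta) + W11(m, m) * old;
          double nb = 0.0;
          if (g > rho) nb = (g - rho) / W11(m, m);
          else if (g < -rho) nb = (g + rho) / W11(m, m);
          if (nb != old) {
            beta[m] = nb;
            del = std::max(del, std::fabs(nb - old));
          }
        }
        if (del < innerTol) break;
      }
      B.col(j) = beta;
      vec w12 = W11 * beta;
      double change = 0.0;
      for (int m = 0; m < p - 1; ++m) {
        change += std::fabs(W(idx[m], j) - w12[m]);
        W(idx[m], j) = w12[m];
        W(j, idx[m]) = w12[m];
      }
      meanChange += change / std::max(1, p - 1);
    }
    meanChange /= p;
    if (meanChange < thr) { converged = true; ++it; break; }
  }

  // recover Theta from the final W and regression coefficients
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx(p - 1);
    int k = 0;
    for (int i = 0; i < p; ++i) if (i != j) idx[k++] = i;
    vec beta = B.col(j);
    vec w12 = W.col(j);
    double denom = W(j, j) - dot(w12.elem(idx), beta);
    double t22 = 1.0 / denom;
    Theta(j, j) = t22;
    for (int m = 0; m < p - 1; ++m) Theta(idx[m], j) = -beta[m] * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
    Rcpp::Named("theta") = Theta,
    Rcpp::Named("w") = W,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}
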