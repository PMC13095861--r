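// Graphical lasso: L1-penalized inverse-covariance estimation by block
// coordinate descent (Friedman/Hastie/Tibshirani style), with a coordinate
// descent lasso inner solver. The diagonal is unpenalized. Written for the
// per-window regime of dFNC estimation: small p, very many solves.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      int max_iter = 100, double tol = 1e-4) {
  const int p = S.n_rows;
  if (p == 1) {
    arma::mat w(1, 1), th(1, 1);
    w(0, 0) = S(0, 0);
    th(0, 0) = 1.0 / S(0, 0);
    return Rcpp::List::create(Rcpp::Named("w") = w, Rcpp::Named("theta") = th,
                              Rcpp::Named("converged") = true,
                              Rcpp::Named("iterations") = 0);
  }
  arma::mat W = S;                 // covariance estimate, diagonal fixed at S_ii
  arma::mat B(p - 1, p, arma::fill::zeros); // lasso coefficients per column
  const double off_mean =
      (arma::accu(arma::abs(S)) - arma::accu(arma::abs(S.diag()))) /
      (double)(p * (p - 1));
  const double thresh = tol * std::max(off_mean, 1e-12);

  bool converged = false;
  int iter = 0;
  arma::uvec all = arma::regspace<arma::uvec>(0, p - 1);
  for (iter = 1; iter <= max_iter; ++iter) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      arma::uvec idx = arma::find(all != (unsigned)j);
      arma::mat W11 = W.submat(idx, idx);
      arma::vec s12 = S.col(j);
      s12 = s12.elem(idx);
      arma::vec b = B.col(j);
      // lasso coordinate descent: 0.5 b'W11 b - b's12 + lambda|b|_1
      for (int inner = 0; inner < 100; ++inner) {
        double db_max = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double grad = s12(k) - arma::dot(W11.col(k), b) + W11(k, k) * b(k);
          double bnew = soft(grad, lambda) / W11(k, k);
          double db = std::abs(bnew - b(k));
          if (db > db_max) db_max = db;
          b(k) = bnew;
        }
        if (db_max < 1e-7) break;
      }
      B.col(j) = b;
      arma::vec w12 = W11 * b;
      for (int k = 0; k < p - 1; ++k) {
        int row = idx(k);
        double d = std::abs(W(row, j) - w12(k));
        if (d > max_delta) max_delta = d;
        W(row, j) = w12(k);
        W(j, row) = w12(k);
      }
    }
    if (max_delta < thresh) { converged = true; break; }
  }

  // Recover the precision matrix from the final coefficients.
  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    arma::uvec idx = arma::find(all != (unsigned)j);
    arma::vec b = B.col(j);
    arma::vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double denom = W(j, j) - arma::dot(w12, b);
    double t22 = 1.0 / denom;
    Theta(j, j) = t22;
    for (int k = 0; k < p - 1; ++k) {
      Theta(idx(k), j) = -b(k) * t22;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("w") = W, Rcpp::Named("theta") = Theta,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("iterations") = iter);
}
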