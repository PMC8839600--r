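#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// RBF kernel matrix K(x_i, z_j) = exp(-gamma * ||x_i - z_j||^2).
static arma::mat rbf_kernel(const arma::mat& X, const arma::mat& Z,
                            const double gamma) {
  arma::vec xs = arma::sum(arma::square(X), 1);
  arma::vec zs = arma::sum(arma::square(Z), 1);
  arma::mat D = arma::repmat(xs, 1, Z.n_rows) +
                arma::repmat(zs.t(), X.n_rows, 1) - 2.0 * X * Z.t();
  return arma::exp(-gamma * arma::clamp(D, 0.0, arma::datum::inf));
}

// Soft-margin C-SVC dual solved by sequential minimal optimization with
// maximal-violating-pair working-set selection (first-order, no
// shrinking).  y must be +1/-1.  Returns alpha, rho (decision function is
// f(x) = sum_i alpha_i y_i K(x_i, x) - rho) and the iteration count.
// [[Rcpp::export]]
List svm_smo_cpp(const arma::mat& X, const arma::vec& y,
                 const double C, const double gamma,
                 const double eps = 1e-3, const int max_iter = 200000) {
  const int n = X.n_rows;
  if ((int)y.n_elem != n) stop("X and y sizes disagree");
  const double tau = 1e-12;

  arma::mat K = rbf_kernel(X, X, gamma);
  arma::mat Q = K % (y * y.t());
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec G(n, arma::fill::ones);
  G *= -1.0;  // gradient of 0.5 a'Qa - e'a at a = 0

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working set: i maximizes -y G over I_up, j minimizes it over I_low
    int i = -1, j = -1;
    double gmax = -arma::datum::inf, gmin = arma::datum::inf;
    for (int t = 0; t < n; ++t) {
      const double v = -y(t) * G(t);
      const bool up  = (y(t) > 0 && alpha(t) < C) || (y(t) < 0 && alpha(t) > 0);
      const bool low = (y(t) > 0 && alpha(t) > 0) || (y(t) < 0 && alpha(t) < C);
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    const double old_ai = alpha(i), old_aj = alpha(j);
    if (y(i) != y(j)) {
      double quad = Q(i, i) + Q(j, j) + 2.0 * Q(i, j);
      if (quad <= 0) quad = tau;
      const double delta = (-G(i) - G(j)) / quad;
      const double diff = alpha(i) - alpha(j);
      alpha(i) += delta; alpha(j) += delta;
      if (diff > 0) {
        if (alpha(j) < 0) { alpha(j) = 0; alpha(i) = diff; }
        if (alpha(i) > C) { alpha(i) = C; alpha(j) = C - diff; }
      } else {
        if (alpha(i) < 0) { alpha(i) = 0; alpha(j) = -diff; }
        if (alpha(j) > C) { alpha(j) = C; alpha(i) = C + diff; }
      }
    } else {
      double quad = Q(i, i) + Q(j, j) - 2.0 * Q(i, j);
      if (quad <= 0) quad = tau;
      const double delta = (G(i) - G(j)) / quad;
      const double sum = alpha(i) + alpha(j);
      alpha(i) -= delta; alpha(j) += delta;
      if (sum > C) {
        if (alpha(i) > C) { alpha(i) = C; alpha(j) = sum - C; }
        if (alpha(j) > C) { alpha(j) = C; alpha(i) = sum - C; }
      } else {
        if (alpha(j) < 0) { alpha(j) = 0; alpha(i) = sum; }
        if (alpha(i) < 0) { alpha(i) = 0; alpha(j) = sum; }
      }
    }
    G += Q.col(i) * (alpha(i) - old_ai) + Q.col(j) * (alpha(j) - old_aj);
  }

  // rho from KKT conditions: y_t G_t for free support vectors, else the
  // midpoint of the feasible interval.
  double rho;
  int nfree = 0; double sfree = 0.0;
  double ub = arma::datum::inf, lb = -arma::datum::inf;
  for (int t = 0; t < n; ++t) {
    const double v = y(t) * G(t);
    if (alpha(t) > 0 && alpha(t) < C) { ++nfree; sfree += v; }
    else if ((y(t) > 0 && alpha(t) <= 0) || (y(t) < 0 && alpha(t) >= C)) {
      ub = std::min(ub, v);
    } else {
      lb = std::max(lb, v);
    }
  }
  rho = nfree > 0 ? sfree / nfree : (ub + lb) / 2.0;

  return List::create(_["alpha"] = alpha, _["rho"] = rho,
                      _["iterations"] = iter);
}

// Decision values f(x) = sum_i alpha_i y_i K(x_i, x) - rho for new rows.
// [[Rcpp::export]]
arma::vec svm_decision_cpp(const arma::mat& Xtrain, const arma::vec& y,
                           const arma::vec& alpha, const double rho,
                           const double gamma, const arma::mat& Xnew) {
  arma::mat K = rbf_kernel(Xnew, Xtrain, gamma);
  return K * (alpha % y) - rho;
}
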