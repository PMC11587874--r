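// L1-penalized maximum-entropy (presence-background) solver.
//
// Maximizes  f(lambda) = mean_presence(eta) - log sum_background exp(eta)
//                        - sum_j beta_j |lambda_j|
// with eta = X lambda, via FISTA (proximal gradient with Nesterov momentum,
// backtracking line search and adaptive restart).  The smooth part is
// concave, so the maximizer is unique up to features with identical columns.
// Linearity of eta in lambda lets the momentum point's eta be formed from
// stored eta vectors without an extra matrix-vector product.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double logsumexp(const vec& x) {
  double m = x.max();
  return m + std::log(accu(exp(x - m)));
}

// [[Rcpp::export]]
Rcpp::List maxent_fit_cpp(const arma::mat& Xp, const arma::mat& Xb,
                          const arma::vec& beta, double tol = 1e-7,
                          int maxit = 5000, arma::vec lambda0 = arma::vec()) {
  const uword p = Xb.n_cols;
  vec c = mean(Xp, 0).t();            // presence feature means
  vec b = (lambda0.n_elem == p) ? lambda0 : zeros<vec>(p);
  vec b_prev = b;
  vec eta_b = Xb * b, eta_prev = eta_b;
  double t_mom = 1.0;
  double L = 1.0;

  double obj_prev = (logsumexp(eta_b) - dot(c, b)) + accu(beta % abs(b));
  bool converged = false;
  int it = 0;

  for (it = 1; it <= maxit; ++it) {
    // momentum point (eta formed by linearity)
    double mom = (t_mom - 1.0) / (0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t_mom * t_mom)));
    vec y = b + mom * (b - b_prev);
    vec eta_y = eta_b + mom * (eta_b - eta_prev);
    double ly = logsumexp(eta_y) - dot(c, y);

    vec w = exp(eta_y - logsumexp(eta_y));
    vec g = Xb.t() * w - c;

    vec b_new, eta_new;
    double lnew = 0.0;
    for (int bt = 0; bt < 60; ++bt) {
      vec step = y - g / L;
      vec thr = beta / L;
      b_new = sign(step) % max(abs(step) - thr, zeros<vec>(p));
      eta_new = Xb * b_new;
      lnew = logsumexp(eta_new) - dot(c, b_new);
      vec d = b_new - y;
      double quad = ly + dot(g, d) + 0.5 * L * dot(d, d);
      if (lnew <= quad + 1e-12 * std::abs(quad)) break;
      L *= 2.0;
    }

    double obj = lnew + accu(beta % abs(b_new));

    if (obj > obj_prev + 1e-12) {     // restart: momentum overshot
      t_mom = 1.0;
      b_prev = b;
      eta_prev = eta_b;
      L *= 2.0;
      continue;
    }

    b_prev = b; eta_prev = eta_b;
    b = b_new; eta_b = eta_new;
    t_mom = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t_mom * t_mom));
    L = std::max(L * 0.95, 1e-8);

    double rel = std::abs(obj - obj_prev) / (std::abs(obj_prev) + 1e-10);
    obj_prev = obj;
    if (rel < tol) { converged = true; break; }
  }

  double logZ = logsumexp(eta_b);
  vec w = exp(eta_b - logZ);
  double H = -accu(w % log(w + 1e-300));
  double obj_final = -(logZ - dot(c, b)) - accu(beta % abs(b));

  return Rcpp::List::create(
      Rcpp::Named("lambda") = b,
      Rcpp::Named("objective") = obj_final,
      Rcpp::Named("logZ") = logZ,
      Rcpp::Named("entropy") = H,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged);
}
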