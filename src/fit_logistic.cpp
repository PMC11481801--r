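// Penalised logistic regression by damped Newton iteration.
// Deterministic: starts at the zero vector, no stochastic elements.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double penalised_loglik(const mat& X, const vec& y, const vec& beta,
                               double lambda) {
  vec eta = X * beta;
  // log(1 + exp(eta)) computed stably
  vec lse(eta.n_elem);
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    lse[i] = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
  }
  return dot(y, eta) - accu(lse) - 0.5 * lambda * dot(beta, beta);
}

//' @useDynLib cctrial, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".fit_logistic_cpp")]]
Rcpp::List fit_logistic_cpp(const arma::mat& X, const arma::vec& y,
                            double lambda, double tol = 1e-8,
                            int max_iter = 200) {
  const uword p = X.n_cols;
  vec beta(p, fill::zeros);
  double ll = penalised_loglik(X, y, beta, lambda);
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    vec eta = X * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec grad = X.t() * (y - mu) - lambda * beta;
    if (norm(grad, "inf") < tol) { converged = true; break; }
    vec w = mu % (1.0 - mu);
    mat H = X.t() * (X.each_col() % w);
    H.diag() += lambda;
    vec step = solve(H, grad, solve_opts::likely_sympd);
    // step halving keeps the ascent monotone on near-separable data
    double t = 1.0;
    vec beta_new = beta + step;
    double ll_new = penalised_loglik(X, y, beta_new, lambda);
    int halvings = 0;
    while (!(ll_new >= ll - 1e-12) && halvings < 40) {
      t *= 0.5;
      beta_new = beta + t * step;
      ll_new = penalised_loglik(X, y, beta_new, lambda);
      ++halvings;
    }
    beta = beta_new;
    ll = ll_new;
  }

  return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                            Rcpp::Named("loglik") = ll,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = converged);
}
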