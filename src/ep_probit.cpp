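// Expectation propagation for binary Gaussian process classification with
// a probit likelihood.  Site updates follow the standard moment-matching
// scheme with rank-1 posterior updates inside each sweep and a full
// Cholesky-based recomputation at the end of every sweep for numerical
// stability.  Damped updates keep the fixed-point iteration stable on
// near-separable problems.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// log Phi(z), numerically stable via R's pnorm
static inline double log_phi(double z) {
  return R::pnorm(z, 0.0, 1.0, 1, 1);
}

// [[Rcpp::export]]
Rcpp::List ep_probit_fit(const arma::mat& K, const arma::vec& y,
                         double tol, int max_sweeps, double damping) {
  const int n = K.n_rows;
  vec ttau(n, fill::zeros), tnu(n, fill::zeros);
  mat Sigma = K;
  vec mu(n, fill::zeros);

  double max_delta = datum::inf;
  int sweeps = 0;
  bool converged = false;

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    max_delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double sii = Sigma(i, i);
      double tau_cav = 1.0 / sii - ttau(i);
      double nu_cav = mu(i) / sii - tnu(i);
      if (tau_cav <= 1e-12) tau_cav = 1e-12;  // guard near-singular cavities
      double s2_cav = 1.0 / tau_cav;
      double mu_cav = nu_cav * s2_cav;
      // probit tilted moments
      double denom = std::sqrt(1.0 + s2_cav);
      double z = y(i) * mu_cav / denom;
      double ratio = std::exp(R::dnorm(z, 0.0, 1.0, 1) - log_phi(z));
      double mu_hat = mu_cav + y(i) * s2_cav * ratio / denom;
      double s2_hat = s2_cav -
        s2_cav * s2_cav * ratio / (1.0 + s2_cav) * (z + ratio);
      if (s2_hat <= 1e-12) s2_hat = 1e-12;
      double tau_prop = 1.0 / s2_hat - tau_cav;
      double nu_prop = mu_hat / s2_hat - nu_cav;
      if (tau_prop < 0.0) tau_prop = 0.0;  // site precisions stay >= 0
      double dtau = damping * (tau_prop - ttau(i));
      double dnu = damping * (nu_prop - tnu(i));
      if (ttau(i) + dtau < 0.0) dtau = -ttau(i);
      ttau(i) += dtau;
      tnu(i) += dnu;
      max_delta = std::max(max_delta, std::max(std::fabs(dtau),
                                               std::fabs(dnu)));
      // rank-1 update of the approximate posterior
      vec si = Sigma.col(i);
      Sigma -= (dtau / (1.0 + dtau * sii)) * (si * si.t());
      mu = Sigma * tnu;
    }
    // stable recomputation: B = I + S^{1/2} K S^{1/2}
    vec sW = sqrt(ttau);
    mat B = eye(n, n) + (sW * sW.t()) % K;
    mat L;
    if (!chol(L, B, "lower")) {
      Rcpp::stop("EP posterior recomputation failed: B not positive definite");
    }
    mat V = solve(trimatl(L), K.each_col() % sW);
    Sigma = K - V.t() * V;
    mu = Sigma * tnu;
    ++sweeps;
    if (max_delta < tol) { converged = true; break; }
  }

  // final factors and approximate log marginal likelihood
  vec sW = sqrt(ttau);
  mat B = eye(n, n) + (sW * sW.t()) % K;
  mat L = chol(B, "lower");
  mat V = solve(trimatl(L), K.each_col() % sW);
  mat Sig = K - V.t() * V;
  mu = Sig * tnu;
  vec sig_d = Sig.diag();
  vec tau_cav = 1.0 / sig_d - ttau;
  tau_cav = clamp(tau_cav, 1e-12, datum::inf);
  vec nu_cav = mu / sig_d - tnu;
  vec mu_cav = nu_cav / tau_cav;
  vec s2_cav = 1.0 / tau_cav;

  double lZ_sites = 0.0;
  for (int i = 0; i < n; ++i) {
    lZ_sites += log_phi(y(i) * mu_cav(i) / std::sqrt(1.0 + s2_cav(i)));
  }
  double lml = lZ_sites - accu(log(L.diag())) +
    0.5 * accu(log(1.0 + ttau % s2_cav)) +
    0.5 * dot(tnu, Sig * tnu) +
    0.5 * dot(nu_cav, (ttau % nu_cav % s2_cav - 2.0 * tnu) /
              (tau_cav + ttau)) -
    0.5 * accu(square(tnu) / (tau_cav + ttau));

  // alpha such that the latent predictive mean at x* is k(x*)' alpha
  vec alpha = tnu - sW % solve(trimatu(L.t()),
                               solve(trimatl(L), sW % (K * tnu)));

  return Rcpp::List::create(
    Rcpp::Named("tau_site") = ttau,
    Rcpp::Named("nu_site") = tnu,
    Rcpp::Named("alpha") = alpha,
    Rcpp::Named("L") = L,
    Rcpp::Named("sW") = sW,
    Rcpp::Named("lml") = lml,
    Rcpp::Named("sweeps") = sweeps,
    Rcpp::Named("max_delta") = max_delta,
    Rcpp::Named("converged") = converged);
}

// Predictive probability of the positive class for a block of test
// points.  Kstar is n x m (train-test kernel), kss the m test
// self-covariances.
// [[Rcpp::export]]
Rcpp::List ep_probit_predict(const arma::mat& L, const arma::vec& sW,
                             const arma::vec& alpha, const arma::mat& Kstar,
                             const arma::vec& kss) {
  const int m = Kstar.n_cols;
  vec fmean = Kstar.t() * alpha;
  mat Vv = solve(trimatl(L), Kstar.each_col() % sW);
  vec fvar(m);
  for (int j = 0; j < m; ++j) {
    fvar(j) = kss(j) - dot(Vv.col(j), Vv.col(j));
  }
  int clamped = 0;
  for (int j = 0; j < m; ++j) {
    if (fvar(j) < 0) { fvar(j) = 0; ++clamped; }
  }
  vec p(m);
  for (int j = 0; j < m; ++j) {
    p(j) = R::pnorm(fmean(j) / std::sqrt(1.0 + fvar(j)), 0.0, 1.0, 1, 0);
  }
  return Rcpp::List::create(Rcpp::Named("prob") = p,
                            Rcpp::Named("latent_mean") = fmean,
                            Rcpp::Named("latent_var") = fvar,
                            Rcpp::Named("n_clamped") = clamped);
}
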