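// Gibbs sampler for the stochastic Gompertz state-space model:
//   x[t+1] = x[t] + r - b*x[t] + c*z[t] + eps[t],  eps ~ N(0, tau^2)
//   y[t]   = x[t] + eta[t],                        eta ~ N(0, sigma^2)
// Latent states are drawn by forward-filter backward-sampling (the model is
// conditionally linear-Gaussian); (r, b, c) jointly by a conjugate normal
// regression update; tau^2 and sigma^2 by truncated inverse-gamma updates
// implied by uniform priors on tau and sigma over (0, sd_max).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// draw v = 1/u with u ~ Gamma(shape, rate) truncated to u >= 1/(sd_max^2),
// i.e. an inverse-gamma draw truncated to (0, sd_max^2)
static double rinvgamma_trunc(double shape, double rate, double sd_max) {
  double scale = 1.0 / rate;
  double lo = R::pgamma(1.0 / (sd_max * sd_max), shape, scale, 1, 0);
  double p = R::runif(lo, 1.0);
  if (p >= 1.0) p = 1.0 - 1e-12;
  double u = R::qgamma(p, shape, scale, 1, 0);
  if (u < 1e-300) u = 1e-300;
  return 1.0 / u;
}

// [[Rcpp::export]]
List gompertz_gibbs_cpp(NumericVector y, NumericVector z,
                        int n_iter, int n_burn,
                        double prior_r_mean, double prior_r_sd,
                        double prior_bc_sd, double sd_max,
                        double x1_prior_sd,
                        bool sigma_zero, bool save_states) {
  const int T = y.size();
  const int n1 = T - 1;
  arma::vec x(T), m(T), C(T), a(T), R(T);
  for (int t = 0; t < T; ++t) x[t] = y[t];

  // initial parameter values: least-squares-flavoured starting point
  double r = prior_r_mean, b = 0.0, c = 0.0;
  double tau2 = 0.01, sigma2 = sigma_zero ? 0.0 : 0.01;

  arma::mat P0 = arma::zeros(3, 3);
  P0(0, 0) = 1.0 / (prior_r_sd * prior_r_sd);
  P0(1, 1) = 1.0 / (prior_bc_sd * prior_bc_sd);
  P0(2, 2) = 1.0 / (prior_bc_sd * prior_bc_sd);
  arma::vec m0 = {prior_r_mean, 0.0, 0.0};

  NumericVector out_r(n_iter), out_b(n_iter), out_c(n_iter),
      out_tau(n_iter), out_sigma(n_iter);
  NumericMatrix out_x(save_states ? n_iter : 1, T);

  arma::mat X(n1, 3);
  arma::vec d(n1);

  for (int it = 0; it < n_iter + n_burn; ++it) {
    double phi = 1.0 - b;

    if (sigma_zero) {
      for (int t = 0; t < T; ++t) x[t] = y[t];
    } else {
      // forward filter
      double a1 = y[0], R1 = x1_prior_sd * x1_prior_sd;
      for (int t = 0; t < T; ++t) {
        double at, Rt;
        if (t == 0) { at = a1; Rt = R1; }
        else {
          at = r + phi * m[t - 1] + c * z[t - 1];
          Rt = phi * phi * C[t - 1] + tau2;
        }
        double Q = Rt + sigma2;
        double K = (Q > 0.0) ? Rt / Q : 0.0;
        a[t] = at; R[t] = Rt;
        m[t] = at + K * (y[t] - at);
        C[t] = Rt - K * Rt;
        if (C[t] < 0.0) C[t] = 0.0;
      }
      // backward sample
      x[T - 1] = m[T - 1] + sqrt(C[T - 1]) * R::norm_rand();
      for (int t = T - 2; t >= 0; --t) {
        double Rn = R[t + 1];
        double J = (Rn > 0.0) ? C[t] * phi / Rn : 0.0;
        double h = m[t] + J * (x[t + 1] - a[t + 1]);
        double V = C[t] - J * J * Rn;
        if (V < 0.0) V = 0.0;
        x[t] = h + sqrt(V) * R::norm_rand();
      }
    }

    // conjugate joint update of (r, b, c) given states and tau^2
    for (int t = 0; t < n1; ++t) {
      d[t] = x[t + 1] - x[t];
      X(t, 0) = 1.0;
      X(t, 1) = -x[t];
      X(t, 2) = z[t];
    }
    arma::mat A = X.t() * X / tau2 + P0;
    arma::vec bvec = X.t() * d / tau2 + P0 * m0;
    arma::mat Ainv = arma::inv_sympd(arma::symmatu(A));
    arma::vec mu = Ainv * bvec;
    arma::mat L = arma::chol(arma::symmatu(Ainv), "lower");
    arma::vec zdraw(3);
    for (int j = 0; j < 3; ++j) zdraw[j] = R::norm_rand();
    arma::vec beta = mu + L * zdraw;
    r = beta[0]; b = beta[1]; c = beta[2];

    // tau^2 | states, params : truncated inverse gamma
    double ss = 0.0;
    for (int t = 0; t < n1; ++t) {
      double e = d[t] - r + b * x[t] - c * z[t];
      ss += e * e;
    }
    if (ss < 1e-12) ss = 1e-12; // guard for noise-free degenerate series
    tau2 = rinvgamma_trunc((n1 - 1.0) / 2.0, ss / 2.0, sd_max);

    // sigma^2 | states : truncated inverse gamma (unless pinned at 0)
    if (!sigma_zero) {
      double ss2 = 0.0;
      for (int t = 0; t < T; ++t) {
        double e = y[t] - x[t];
        ss2 += e * e;
      }
      if (ss2 < 1e-12) ss2 = 1e-12;
      sigma2 = rinvgamma_trunc((T - 1.0) / 2.0, ss2 / 2.0, sd_max);
    }

    if (it >= n_burn) {
      int k = it - n_burn;
      out_r[k] = r; out_b[k] = b; out_c[k] = c;
      out_tau[k] = sqrt(tau2); out_sigma[k] = sqrt(sigma2);
      if (save_states) {
        for (int t = 0; t < T; ++t) out_x(k, t) = x[t];
      }
    }
  }

  return List::create(_["r"] = out_r, _["b"] = out_b, _["c"] = out_c,
                      _["tau"] = out_tau, _["sigma"] = out_sigma,
                      _["x"] = out_x);
}
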