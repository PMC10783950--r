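#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-cell Gaussian log likelihood: sum_j log N(y_ij | sum_k rho_k mu_kj, prec tau_j)
static double cell_loglik(const NumericMatrix &Y, const NumericMatrix &mu,
                          const NumericVector &tau, const double *rho_i,
                          int i, int K, int J) {
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    double m = 0.0;
    for (int k = 0; k < K; ++k) m += rho_i[k] * mu(k, j);
    double r = Y(i, j) - m;
    ll += 0.5 * (std::log(tau[j]) - std::log(2.0 * M_PI)) - 0.5 * tau[j] * r * r;
  }
  return ll;
}

// One Metropolis sweep over all contribution vectors. Random walk on the
// additive log-ratio (ALR) coordinates of the simplex; the change of
// variables contributes a Jacobian prod_k rho_k, which combined with the
// Dirichlet(kappa) prior gives target exponent kappa on every component
// (finite everywhere, so kappa < 1 is safe). Step sizes are per cell:
// cells whose posteriors sit near a vertex need very different proposal
// scales than cells with genuinely mixed profiles.
// [[Rcpp::export]]
List cpp_step_rho(const NumericMatrix &Y, const NumericMatrix &mu,
                  const NumericVector &tau, const NumericMatrix &rho,
                  double kappa, const NumericVector &step) {
  const int I = Y.nrow(), J = Y.ncol(), K = mu.nrow();
  NumericMatrix out = clone(rho);
  IntegerVector accepts(I);
  std::vector<double> z(K - 1), cur(K), prop(K);
  for (int i = 0; i < I; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      cur[k] = out(i, k) < 1e-10 ? 1e-10 : out(i, k);
      s += cur[k];
    }
    for (int k = 0; k < K; ++k) cur[k] /= s;
    const double loglast = std::log(cur[K - 1]);
    for (int k = 0; k < K - 1; ++k)
      z[k] = std::log(cur[k]) - loglast + step[i] * norm_rand();
    // softmax with implicit last coordinate 0
    double mx = 0.0;
    for (int k = 0; k < K - 1; ++k) if (z[k] > mx) mx = z[k];
    double denom = std::exp(-mx);
    for (int k = 0; k < K - 1; ++k) denom += std::exp(z[k] - mx);
    for (int k = 0; k < K - 1; ++k) prop[k] = std::exp(z[k] - mx) / denom;
    prop[K - 1] = std::exp(-mx) / denom;
    double lt_cur = cell_loglik(Y, mu, tau, cur.data(), i, K, J);
    double lt_prop = cell_loglik(Y, mu, tau, prop.data(), i, K, J);
    for (int k = 0; k < K; ++k) {
      lt_cur += kappa * std::log(cur[k]);
      double pk = prop[k] < 1e-300 ? 1e-300 : prop[k];
      lt_prop += kappa * std::log(pk);
    }
    if (std::log(unif_rand()) < lt_prop - lt_cur) {
      for (int k = 0; k < K; ++k) out(i, k) = prop[k];
      accepts[i] = 1;
    } else {
      for (int k = 0; k < K; ++k) out(i, k) = cur[k];
    }
  }
  return List::create(_["rho"] = out, _["accepts"] = accepts);
}

static NumericMatrix mean_matrix(const NumericMatrix &rho, const NumericMatrix &mu) {
  const int I = rho.nrow(), K = rho.ncol(), J = mu.ncol();
  NumericMatrix M(I, J);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j) {
      double m = 0.0;
      for (int k = 0; k < K; ++k) m += rho(i, k) * mu(k, j);
      M(i, j) = m;
    }
  return M;
}

// Exact draw from each mu_kj full conditional:
// precision tau0 + tau_j * sum_i rho_ik^2,
// mean (tau0 p_kj + tau_j sum_i rho_ik (y_ij - sum_{k'!=k} rho_ik' mu_k'j)) / precision.
// [[Rcpp::export]]
NumericMatrix cpp_step_mu_gibbs(const NumericMatrix &Y, const NumericMatrix &mu,
                                const NumericVector &tau, const NumericMatrix &rho,
                                const NumericMatrix &P, double tau0) {
  const int I = Y.nrow(), J = Y.ncol(), K = mu.nrow();
  NumericMatrix out = clone(mu);
  NumericMatrix M = mean_matrix(rho, out);
  std::vector<double> delta(J);
  for (int k = 0; k < K; ++k) {
    double Sk = 0.0;
    for (int i = 0; i < I; ++i) Sk += rho(i, k) * rho(i, k);
    for (int j = 0; j < J; ++j) {
      double T = 0.0;
      for (int i = 0; i < I; ++i)
        T += rho(i, k) * (Y(i, j) - M(i, j) + rho(i, k) * out(k, j));
      double prec = tau0 + tau[j] * Sk;
      double mean = (tau0 * P(k, j) + tau[j] * T) / prec;
      double nv = mean + norm_rand() / std::sqrt(prec);
      delta[j] = nv - out(k, j);
      out(k, j) = nv;
    }
    for (int i = 0; i < I; ++i)
      for (int j = 0; j < J; ++j) M(i, j) += rho(i, k) * delta[j];
  }
  return out;
}

// Random-walk Metropolis alternative for mu (elementwise Gaussian proposal).
// [[Rcpp::export]]
List cpp_step_mu_mh(const NumericMatrix &Y, const NumericMatrix &mu,
                    const NumericVector &tau, const NumericMatrix &rho,
                    const NumericMatrix &P, double tau0, double step) {
  const int I = Y.nrow(), J = Y.ncol(), K = mu.nrow();
  NumericMatrix out = clone(mu);
  NumericMatrix M = mean_matrix(rho, out);
  int accepts = 0;
  for (int k = 0; k < K; ++k) {
    double Sk = 0.0;
    for (int i = 0; i < I; ++i) Sk += rho(i, k) * rho(i, k);
    for (int j = 0; j < J; ++j) {
      double d = step * norm_rand();
      double T = 0.0;
      for (int i = 0; i < I; ++i) T += rho(i, k) * (Y(i, j) - M(i, j));
      double dll = -0.5 * tau[j] * (d * d * Sk - 2.0 * d * T);
      double cur = out(k, j) - P(k, j);
      double dlp = -0.5 * tau0 * ((cur + d) * (cur + d) - cur * cur);
      if (std::log(unif_rand()) < dll + dlp) {
        out(k, j) += d;
        for (int i = 0; i < I; ++i) M(i, j) += rho(i, k) * d;
        ++accepts;
      }
    }
  }
  return List::create(_["mu"] = out, _["accepts"] = accepts);
}

// Exact draw from each tau_j full conditional:
// Gamma(alpha0 + I/2, rate beta0 + 0.5 sum_i (y_ij - m_ij)^2).
// [[Rcpp::export]]
NumericVector cpp_step_tau_gibbs(const NumericMatrix &Y, const NumericMatrix &mu,
                                 const NumericMatrix &rho,
                                 double alpha0, double beta0) {
  const int I = Y.nrow(), J = Y.ncol();
  NumericMatrix M = mean_matrix(rho, mu);
  NumericVector out(J);
  for (int j = 0; j < J; ++j) {
    double ssr = 0.0;
    for (int i = 0; i < I; ++i) {
      double r = Y(i, j) - M(i, j);
      ssr += r * r;
    }
    out[j] = R::rgamma(alpha0 + 0.5 * I, 1.0 / (beta0 + 0.5 * ssr));
  }
  return out;
}

// Log-scale random-walk Metropolis alternative for tau; Jacobian of the log
// transform folds into the exponent (alpha0 + I/2).
// [[Rcpp::export]]
List cpp_step_tau_mh(const NumericMatrix &Y, const NumericMatrix &mu,
                     const NumericMatrix &rho, const NumericVector &tau,
                     double alpha0, double beta0, double step) {
  const int I = Y.nrow(), J = Y.ncol();
  NumericMatrix M = mean_matrix(rho, mu);
  NumericVector out = clone(tau);
  int accepts = 0;
  for (int j = 0; j < J; ++j) {
    double ssr = 0.0;
    for (int i = 0; i < I; ++i) {
      double r = Y(i, j) - M(i, j);
      ssr += r * r;
    }
    double prop = out[j] * std::exp(step * norm_rand());
    double lr = (alpha0 + 0.5 * I) * (std::log(prop) - std::log(out[j])) -
                (beta0 + 0.5 * ssr) * (prop - out[j]);
    if (std::log(unif_rand()) < lr) {
      out[j] = prop;
      ++accepts;
    }
  }
  return List::create(_["tau"] = out, _["accepts"] = accepts);
}

// [[Rcpp::export]]
NumericVector cpp_loglik_rows(const NumericMatrix &Y, const NumericMatrix &mu,
                              const NumericVector &tau, const NumericMatrix &rho) {
  const int I = Y.nrow(), J = Y.ncol(), K = mu.nrow();
  NumericVector out(I);
  std::vector<double> r(K);
  for (int i = 0; i < I; ++i) {
    for (int k = 0; k < K; ++k) r[k] = rho(i, k);
    out[i] = cell_loglik(Y, mu, tau, r.data(), i, K, J);
  }
  return out;
}
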