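// Gibbs samplers for whole-genome Bayesian marker regressions.
// BayesC: spike-slab marker effects (point mass at zero, Gaussian slab with a
// common scaled-inverse-chi-square variance), fixed inclusion probability pi.
// Bayesian LASSO: double-exponential effect prior via the normal-exponential
// scale mixture with a Gamma-updated lambda^2 (Park & Casella
// parameterization, effects scaled by the residual variance).
// Uses R's RNG so chains are reproducible under set.seed().
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// scaled-inverse-chi-square draw: (df * scale) / chisq_df
double rscinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// inverse-Gaussian(mu, lambda) via Michael, Schucany & Haas
double rinvgauss(double mu, double lambda) {
  double v = norm_rand();
  double y = v * v;
  double x = mu + mu * mu * y / (2.0 * lambda)
             - mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

} // namespace

// [[Rcpp::export]]
List cpp_bayesc(NumericMatrix X, NumericVector y, int n_iter, int burn_in,
                double pi_in, double df_b, double scale_b,
                double df_e, double scale_e) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  double mu = mean(y);
  std::vector<double> beta(p, 0.0), e(n);
  std::vector<int> delta(p, 0);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double vb = scale_b, ve = scale_e;

  NumericVector beta_mean(p), pip(p);
  double mu_mean = 0.0, vb_mean = 0.0, ve_mean = 0.0;
  int kept = 0;
  const double log_pi = std::log(pi_in), log_1mpi = std::log(1.0 - pi_in);

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double se = 0.0;
    for (int i = 0; i < n; ++i) se += e[i] + mu;
    double mu_new = se / n + norm_rand() * std::sqrt(ve / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    int m_in = 0;
    double ssb = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0) continue;
      double rhs = xtx[j] * beta[j];
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      // marginal likelihood of rhs under exclusion / inclusion
      double v0 = xtx[j] * ve;
      double v1 = xtx[j] * xtx[j] * vb + xtx[j] * ve;
      double logL0 = -0.5 * (std::log(v0) + rhs * rhs / v0) + log_1mpi;
      double logL1 = -0.5 * (std::log(v1) + rhs * rhs / v1) + log_pi;
      double prob1 = 1.0 / (1.0 + std::exp(logL0 - logL1));
      double bnew = 0.0;
      int dnew = (unif_rand() < prob1) ? 1 : 0;
      if (dnew) {
        double c = xtx[j] + ve / vb;
        bnew = rhs / c + norm_rand() * std::sqrt(ve / c);
      }
      if (bnew != beta[j]) {
        double diff = bnew - beta[j];
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * diff;
        beta[j] = bnew;
      }
      delta[j] = dnew;
      if (dnew) { ++m_in; ssb += bnew * bnew; }
    }

    vb = rscinvchisq(df_b + m_in, (df_b * scale_b + ssb) / (df_b + m_in));
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    ve = rscinvchisq(df_e + n, (df_e * scale_e + sse) / (df_e + n));

    if (it >= burn_in) {
      ++kept;
      for (int j = 0; j < p; ++j) {
        beta_mean[j] += beta[j];
        pip[j] += delta[j];
      }
      mu_mean += mu; vb_mean += vb; ve_mean += ve;
    }
  }
  for (int j = 0; j < p; ++j) { beta_mean[j] /= kept; pip[j] /= kept; }
  return List::create(_["beta"] = beta_mean, _["pip"] = pip,
                      _["mu"] = mu_mean / kept, _["sigma2_b"] = vb_mean / kept,
                      _["sigma2_e"] = ve_mean / kept, _["n_kept"] = kept);
}

// [[Rcpp::export]]
List cpp_blasso(NumericMatrix X, NumericVector y, int n_iter, int burn_in,
                double lambda2_init, double gamma_shape, double gamma_rate,
                double df_e, double scale_e) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  double mu = mean(y);
  std::vector<double> beta(p, 0.0), e(n), tau2(p, 1.0);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double ve = scale_e, lambda2 = lambda2_init;

  NumericVector beta_mean(p);
  double mu_mean = 0.0, ve_mean = 0.0, l2_mean = 0.0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    double se = 0.0;
    for (int i = 0; i < n; ++i) se += e[i] + mu;
    double mu_new = se / n + norm_rand() * std::sqrt(ve / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    double sum_tau2 = 0.0, ssb_scaled = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0) continue;
      double rhs = xtx[j] * beta[j];
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      double c = xtx[j] + 1.0 / tau2[j];
      double bnew = rhs / c + norm_rand() * std::sqrt(ve / c);
      double diff = bnew - beta[j];
      for (int i = 0; i < n; ++i) e[i] -= X(i, j) * diff;
      beta[j] = bnew;
      // 1/tau2 | rest ~ InvGauss(sqrt(lambda2 * ve / beta^2), lambda2)
      double b2 = beta[j] * beta[j];
      if (b2 < 1e-14) b2 = 1e-14;
      double inv_tau2 = rinvgauss(std::sqrt(lambda2 * ve / b2), lambda2);
      tau2[j] = 1.0 / inv_tau2;
      sum_tau2 += tau2[j];
      ssb_scaled += b2 / tau2[j];
    }

    lambda2 = R::rgamma(gamma_shape + p, 1.0 / (gamma_rate + sum_tau2 / 2.0));

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    ve = rscinvchisq(df_e + n + p, (df_e * scale_e + sse + ssb_scaled) / (df_e + n + p));

    if (it >= burn_in) {
      ++kept;
      for (int j = 0; j < p; ++j) beta_mean[j] += beta[j];
      mu_mean += mu; ve_mean += ve; l2_mean += lambda2;
    }
  }
  for (int j = 0; j < p; ++j) beta_mean[j] /= kept;
  return List::create(_["beta"] = beta_mean, _["mu"] = mu_mean / kept,
                      _["sigma2_e"] = ve_mean / kept,
                      _["lambda2"] = l2_mean / kept, _["n_kept"] = kept);
}
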