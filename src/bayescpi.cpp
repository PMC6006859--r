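#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Single-site Gibbs sampler for BayesCpi: y = 1*mu + X*beta + sum_k gamma_k
// w_k alpha_k + e, with a point-mass/normal mixture on marker effects, one
// common effect variance sigma2_alpha, scaled-inverse-chi-square priors on
// both variances, flat priors on mu/beta, and a uniform prior on the
// exclusion probability pi (Beta full conditional). Genotype columns enter
// raw (0/1/2); the intercept absorbs the mean.
//
// The update flags exist so that degenerate configurations (fixed variances,
// fixed pi, no intercept) can be checked against conjugate closed forms and
// exhaustive model enumeration.
// [[Rcpp::export]]
List cpp_bayescpi(NumericVector y, NumericMatrix W, NumericMatrix X,
                  double S2a, double nua, double S2e, double nue,
                  int chain_length, int burn_in,
                  double pi_init, double sigma2a_init, double sigma2e_init,
                  bool update_mu, bool update_pi,
                  bool update_sigma2a, bool update_sigma2e,
                  int thin_store) {
  int n = y.size();
  int p = W.ncol();
  int q = X.ncol();
  if (W.nrow() != n || (q > 0 && X.nrow() != n))
    stop("dimension mismatch between y, W, X");
  if (burn_in >= chain_length) stop("burn_in must be smaller than chain_length");

  std::vector<double> wtw(p), xtx(q);
  for (int k = 0; k < p; ++k) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += W(i, k) * W(i, k);
    wtw[k] = s;
  }
  for (int j = 0; j < q; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    if (s <= 0) stop("constant-zero covariate column");
    xtx[j] = s;
  }

  double mu = 0.0, pi = pi_init;
  double s2a = sigma2a_init, s2e = sigma2e_init;
  std::vector<double> alpha(p, 0.0), beta(q, 0.0);
  std::vector<int> gamma(p, 0);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  std::vector<double> pip(p, 0.0), alpha_mean(p, 0.0);
  int n_keep = chain_length - burn_in;
  int n_store = (chain_length + thin_store - 1) / thin_store;
  NumericMatrix trace(n_store, 4);  // sigma2e, sigma2a, pi, model size
  int stored = 0;

  for (int it = 0; it < chain_length; ++it) {
    if (update_mu) {
      double s = 0;
      for (int i = 0; i < n; ++i) s += e[i] + mu;
      double mu_new = s / n + norm_rand() * std::sqrt(s2e / n);
      double d = mu_new - mu;
      for (int i = 0; i < n; ++i) e[i] -= d;
      mu = mu_new;
    }
    for (int j = 0; j < q; ++j) {
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xtx[j] * beta[j];
      double b_new = rhs / xtx[j] + norm_rand() * std::sqrt(s2e / xtx[j]);
      double d = b_new - beta[j];
      for (int i = 0; i < n; ++i) e[i] -= d * X(i, j);
      beta[j] = b_new;
    }
    int m_in = 0;
    double ssa = 0;
    for (int k = 0; k < p; ++k) {
      double c = wtw[k];
      if (c <= 0) { gamma[k] = 0; alpha[k] = 0; continue; }
      double rhs = 0;
      const double* wk = &W(0, k);
      if (gamma[k]) {
        double ak = alpha[k];
        for (int i = 0; i < n; ++i) rhs += wk[i] * (e[i] + wk[i] * ak);
      } else {
        for (int i = 0; i < n; ++i) rhs += wk[i] * e[i];
      }
      double v1 = c * s2a + s2e;
      double log_odds = std::log((1.0 - pi) / pi) +
        0.5 * std::log(s2e / v1) + 0.5 * rhs * rhs * s2a / (s2e * v1);
      double pr_in;
      if (!update_pi && pi <= 0.0) pr_in = 1.0;
      else if (!update_pi && pi >= 1.0) pr_in = 0.0;
      else pr_in = 1.0 / (1.0 + std::exp(-log_odds));
      int g_new = (unif_rand() < pr_in) ? 1 : 0;
      double a_new = 0.0;
      if (g_new) {
        double prec = c / s2e + 1.0 / s2a;
        a_new = rhs / s2e / prec + norm_rand() / std::sqrt(prec);
      }
      if (g_new || gamma[k]) {
        double d = a_new - (gamma[k] ? alpha[k] : 0.0);
        if (d != 0.0)
          for (int i = 0; i < n; ++i) e[i] -= d * wk[i];
      }
      gamma[k] = g_new;
      alpha[k] = a_new;
      if (g_new) { ++m_in; ssa += a_new * a_new; }
    }
    if (update_sigma2a) {
      double df = nua + m_in;
      s2a = (ssa + nua * S2a) / R::rchisq(df);
    }
    if (update_sigma2e) {
      double sse = 0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      s2e = (sse + nue * S2e) / R::rchisq(nue + n);
      if (!R_finite(s2e) || s2e <= 0) stop("residual variance diverged");
    }
    if (update_pi) pi = R::rbeta(p - m_in + 1.0, m_in + 1.0);
    if (it >= burn_in) {
      for (int k = 0; k < p; ++k) {
        pip[k] += gamma[k];
        alpha_mean[k] += alpha[k];
      }
    }
    if (it % thin_store == 0) {
      trace(stored, 0) = s2e;
      trace(stored, 1) = s2a;
      trace(stored, 2) = pi;
      trace(stored, 3) = m_in;
      ++stored;
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector pip_out(p), am_out(p);
  for (int k = 0; k < p; ++k) {
    pip_out[k] = pip[k] / n_keep;
    am_out[k] = alpha_mean[k] / n_keep;
  }
  return List::create(_["pip"] = pip_out, _["alpha_mean"] = am_out,
                      _["trace"] = trace, _["n_stored"] = stored);
}

// Monte-Carlo cycles for the sliding-window effective-number-of-tests
// estimator. z_j is generated sequentially; its conditional mean is a linear
// combination of the previous m_j draws (lag-ordered coefficients in column j
// of B) and its conditional sd is sd_j. Returns the genome-wide max |z| per
// cycle.
// [[Rcpp::export]]
NumericVector cpp_slide_max(NumericMatrix B, IntegerVector m, NumericVector sd,
                            int n_cycles) {
  int p = m.size();
  NumericVector out(n_cycles);
  std::vector<double> z(p);
  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    double mx = 0;
    for (int j = 0; j < p; ++j) {
      double mean = 0;
      int mj = m[j];
      for (int t = 1; t <= mj; ++t) mean += B(t - 1, j) * z[j - t];
      z[j] = mean + sd[j] * norm_rand();
      double az = std::fabs(z[j]);
      if (az > mx) mx = az;
    }
    out[cyc] = mx;
    if ((cyc & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
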