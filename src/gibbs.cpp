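// Gibbs samplers for whole-genome regression: ridge-type (rrBLUP, common
// marker-effect variance) and BayesB (per-marker point mass at zero plus
// scaled-t slab).  All randomness goes through R's RNG so set.seed() in the
// calling R code makes fits reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static double rinvchisq(double df, double scale) {
  // scaled inverse chi-square draw: df*scale / chisq(df)
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export]]
List gibbs_rrblup_cpp(const NumericMatrix& X, const NumericMatrix& F,
                      const NumericVector& y, int n_iter, int burn_in,
                      bool fix_variances, double sigma_b2_fix,
                      double sigma_e2_fix, double df_prior, double R2) {
  const int n = X.nrow(), p = X.ncol(), q = F.ncol();
  NumericVector beta(p), b(q), e = clone(y);
  NumericVector cX(p), cF(q);
  double msx = 0.0;
  for (int j = 0; j < p; ++j) {
    double s = 0, m = 0;
    for (int i = 0; i < n; ++i) { s += X(i, j) * X(i, j); m += X(i, j); }
    cX[j] = s;
    msx += (s - m * m / n) / n;
  }
  for (int k = 0; k < q; ++k) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += F(i, k) * F(i, k);
    cF[k] = s;
  }
  double vy = Rcpp::var(y);
  if (vy <= 0) vy = 1e-8;
  if (msx <= 0) msx = 1e-8;
  double Se = vy * (1.0 - R2) * (df_prior + 2.0);
  double Sb = vy * R2 / msx * (df_prior + 2.0);
  double sigma_e2 = fix_variances ? sigma_e2_fix : vy * (1.0 - R2);
  double sigma_b2 = fix_variances ? sigma_b2_fix : vy * R2 / msx;

  NumericVector beta_mean(p), b_mean(q);
  double se2_mean = 0, sb2_mean = 0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int k = 0; k < q; ++k) {          // fixed effects, flat prior
      if (cF[k] <= 0) continue;
      double rhs = cF[k] * b[k];
      for (int i = 0; i < n; ++i) rhs += F(i, k) * e[i];
      double newb = R::rnorm(rhs / cF[k], std::sqrt(sigma_e2 / cF[k]));
      double d = b[k] - newb;
      for (int i = 0; i < n; ++i) e[i] += F(i, k) * d;
      b[k] = newb;
    }
    double lambda = sigma_e2 / sigma_b2;
    for (int j = 0; j < p; ++j) {
      if (cX[j] <= 0) { beta[j] = 0; continue; }
      double rhs = cX[j] * beta[j];
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      double denom = cX[j] + lambda;
      double newb = R::rnorm(rhs / denom, std::sqrt(sigma_e2 / denom));
      double d = beta[j] - newb;
      for (int i = 0; i < n; ++i) e[i] += X(i, j) * d;
      beta[j] = newb;
    }
    if (!fix_variances) {
      double ssb = 0;
      for (int j = 0; j < p; ++j) ssb += beta[j] * beta[j];
      sigma_b2 = rinvchisq(df_prior + p, (ssb + df_prior * Sb) / (df_prior + p));
      double sse = 0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma_e2 = rinvchisq(df_prior + n, (sse + df_prior * Se) / (df_prior + n));
    }
    if (it >= burn_in) {
      ++kept;
      for (int j = 0; j < p; ++j) beta_mean[j] += beta[j];
      for (int k = 0; k < q; ++k) b_mean[k] += b[k];
      se2_mean += sigma_e2; sb2_mean += sigma_b2;
    }
  }
  for (int j = 0; j < p; ++j) beta_mean[j] /= kept;
  for (int k = 0; k < q; ++k) b_mean[k] /= kept;
  return List::create(_["beta"] = beta_mean, _["b"] = b_mean,
                      _["sigma_e2"] = se2_mean / kept,
                      _["sigma_b2"] = sb2_mean / kept);
}

// [[Rcpp::export]]
List gibbs_bayesb_cpp(const NumericMatrix& X, const NumericMatrix& F,
                      const NumericVector& y, int n_iter, int burn_in,
                      double prob_in_init, double beta_prior_weight,
                      double df_slab, double R2) {
  const int n = X.nrow(), p = X.ncol(), q = F.ncol();
  NumericVector beta(p), b(q), e = clone(y), sj2(p);
  IntegerVector delta(p);
  NumericVector cX(p), cF(q);
  double msx = 0.0;
  for (int j = 0; j < p; ++j) {
    double s = 0, m = 0;
    for (int i = 0; i < n; ++i) { s += X(i, j) * X(i, j); m += X(i, j); }
    cX[j] = s;
    msx += (s - m * m / n) / n;
  }
  for (int k = 0; k < q; ++k) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += F(i, k) * F(i, k);
    cF[k] = s;
  }
  double vy = Rcpp::var(y);
  if (vy <= 0) vy = 1e-8;
  if (msx <= 0) msx = 1e-8;
  double Se = vy * 0.5 * (5.0 + 2.0);
  double Sslab = vy * R2 * (df_slab + 2.0) / (df_slab * msx *
                 std::max(prob_in_init, 0.05));
  double sigma_e2 = vy * (1.0 - R2);
  double prob_in = prob_in_init;
  // Beta hyperprior on the inclusion probability, centred at prob_in_init
  double a_in = beta_prior_weight * prob_in_init;
  double a_out = beta_prior_weight * (1.0 - prob_in_init);
  for (int j = 0; j < p; ++j) { sj2[j] = Sslab; delta[j] = 0; }

  NumericVector beta_mean(p), b_mean(q), incl_freq(p);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int k = 0; k < q; ++k) {
      if (cF[k] <= 0) continue;
      double rhs = cF[k] * b[k];
      for (int i = 0; i < n; ++i) rhs += F(i, k) * e[i];
      double newb = R::rnorm(rhs / cF[k], std::sqrt(sigma_e2 / cF[k]));
      double d = b[k] - newb;
      for (int i = 0; i < n; ++i) e[i] += F(i, k) * d;
      b[k] = newb;
    }
    int n_in = 0;
    for (int j = 0; j < p; ++j) {
      if (delta[j] == 1) {                 // add the marker back to residual
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * beta[j];
      }
      if (cX[j] <= 0) { beta[j] = 0; delta[j] = 0; continue; }
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      double v = cX[j] * sj2[j] + sigma_e2;
      double log_odds = std::log(prob_in / (1.0 - prob_in)) +
        0.5 * (std::log(sigma_e2 / v) + rhs * rhs * sj2[j] / (sigma_e2 * v));
      double p_in = 1.0 / (1.0 + std::exp(-log_odds));
      if (R::unif_rand() < p_in) {
        double denom = cX[j] + sigma_e2 / sj2[j];
        beta[j] = R::rnorm(rhs / denom, std::sqrt(sigma_e2 / denom));
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * beta[j];
        delta[j] = 1; ++n_in;
        sj2[j] = rinvchisq(df_slab + 1.0,
                           (beta[j] * beta[j] + df_slab * Sslab) / (df_slab + 1.0));
      } else {
        beta[j] = 0; delta[j] = 0;
        sj2[j] = rinvchisq(df_slab, Sslab);   // refresh from the prior
      }
    }
    prob_in = R::rbeta(a_in + n_in, a_out + (p - n_in));
    prob_in = std::min(std::max(prob_in, 1e-4), 1.0 - 1e-4);
    double sse = 0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma_e2 = rinvchisq(5.0 + n, (sse + 5.0 * Se) / (5.0 + n));
    if (it >= burn_in) {
      ++kept;
      for (int j = 0; j < p; ++j) {
        beta_mean[j] += beta[j];
        incl_freq[j] += delta[j];
      }
      for (int k = 0; k < q; ++k) b_mean[k] += b[k];
    }
  }
  for (int j = 0; j < p; ++j) { beta_mean[j] /= kept; incl_freq[j] /= kept; }
  for (int k = 0; k < q; ++k) b_mean[k] /= kept;
  return List::create(_["beta"] = beta_mean, _["b"] = b_mean,
                      _["inclusion"] = incl_freq);
}
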