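#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the Bayesian Ridge Regression whole-genome model
//   y = 1 mu + X beta + e,  beta_j ~ N(0, sigma2_b),  e ~ N(0, sigma2_e I)
// with scaled-inverse-chi-square priors on both variance components.
// X is expected column-centered; single-site updates keep a running
// residual vector so one sweep costs O(n p). Draws use R's RNG so results
// are reproducible through set.seed().
//
// [[Rcpp::export(name = ".brr_gibbs")]]
List brr_gibbs(NumericVector y, NumericMatrix Xc,
               int n_iter, int burn_in,
               double df_b, double Sb, double df_e, double Se,
               double mu0, double sigma2_e0, double sigma2_b0,
               bool fix_var, bool keep_beta) {
  const int n = y.size();
  const int p = Xc.ncol();
  const int n_keep = n_iter - burn_in;

  const double* X = Xc.begin();  // column-major
  std::vector<double> beta(p, 0.0), xtx(p);
  for (int j = 0; j < p; ++j) {
    const double* xj = X + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  double mu = mu0, sigma2_e = sigma2_e0, sigma2_b = sigma2_b0;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;  // beta starts at 0

  std::vector<double> beta_sum(p, 0.0);
  double mu_sum = 0.0, se_sum = 0.0, sb_sum = 0.0;
  NumericVector mu_chain(n_keep), se_chain(n_keep), sb_chain(n_keep);
  NumericMatrix beta_chain(keep_beta ? n_keep : 0, keep_beta ? p : 0);

  for (int it = 0; it < n_iter; ++it) {
    // intercept full conditional
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar = (ebar + n * mu) / n;            // mean of y - Xc beta
    double mu_new = ebar + R::rnorm(0.0, std::sqrt(sigma2_e / n));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // marker effects, single-site updates
    const double lambda = sigma2_e / sigma2_b;
    for (int j = 0; j < p; ++j) {
      const double bj = beta[j];
      double rhs = 0.0;
      const double* xj = X + (size_t)j * n;
      for (int i = 0; i < n; ++i) rhs += xj[i] * (e[i] + xj[i] * bj);
      const double C = xtx[j] + lambda;
      const double mean = rhs / C;
      const double b_new = mean + R::rnorm(0.0, std::sqrt(sigma2_e / C));
      const double db = b_new - bj;
      for (int i = 0; i < n; ++i) e[i] -= xj[i] * db;
      beta[j] = b_new;
    }

    if (!fix_var) {
      // scaled-inverse-chi-square full conditionals
      double ssb = 0.0;
      for (int j = 0; j < p; ++j) ssb += beta[j] * beta[j];
      sigma2_b = (ssb + df_b * Sb) / R::rchisq(df_b + p);
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma2_e = (sse + df_e * Se) / R::rchisq(df_e + n);
    }

    if (it >= burn_in) {
      const int k = it - burn_in;
      mu_sum += mu; se_sum += sigma2_e; sb_sum += sigma2_b;
      mu_chain[k] = mu; se_chain[k] = sigma2_e; sb_chain[k] = sigma2_b;
      for (int j = 0; j < p; ++j) beta_sum[j] += beta[j];
      if (keep_beta)
        for (int j = 0; j < p; ++j) beta_chain(k, j) = beta[j];
    }
  }

  NumericVector beta_hat(p);
  for (int j = 0; j < p; ++j) beta_hat[j] = beta_sum[j] / n_keep;

  List out = List::create(
    _["mu_hat"] = mu_sum / n_keep,
    _["beta_hat"] = beta_hat,
    _["sigma2_e"] = se_sum / n_keep,
    _["sigma2_b"] = sb_sum / n_keep,
    _["mu_chain"] = mu_chain,
    _["sigma2_e_chain"] = se_chain,
    _["sigma2_b_chain"] = sb_chain);
  if (keep_beta) out["beta_chain"] = beta_chain;
  return out;
}
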