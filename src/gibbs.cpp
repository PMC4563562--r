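// Gibbs sampler for the probit liability-threshold animal model.
//
// Latent liability l_i ~ N(x_i'beta + u_i, 1) truncated by case status
// (threshold 0, intercept absorbs it); beta from its Gaussian full
// conditional; breeding values u by single-site updates over the sparse
// inverse numerator relationship matrix; sigma2_a from a scaled-inverse-
// chi-square full conditional. Residual variance fixed at 1.
//
// Uses R's RNG so set.seed() in the caller makes chains bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// N(m,1) truncated to (0, Inf), inverse-CDF in the numerically stable tail
static inline double rtnorm_pos(double m) {
  double u = unif_rand();
  // upper-tail probability of the draw: (1-u) * P(N(m,1) > 0)
  double p_up = (1.0 - u) * R::pnorm(m, 0.0, 1.0, 1, 0);
  if (p_up <= 0) p_up = 1e-300;
  return m + R::qnorm(p_up, 0.0, 1.0, 0, 0);
}

// [[Rcpp::export]]
List gibbs_threshold_animal(IntegerVector y, NumericMatrix X,
                            NumericMatrix XtXinv, NumericMatrix Uchol,
                            IntegerVector Ap, IntegerVector Ai,
                            NumericVector Ax,
                            int n_rounds, int burn_in, int thin,
                            double prior_df, double prior_scale,
                            bool use_likelihood) {
  const int n = y.size();
  const int p = X.ncol();
  const int n_keep = (n_rounds - burn_in) / thin;

  std::vector<double> l(n, 0.0), u(n, 0.0), xb(n, 0.0), beta(p, 0.0);
  std::vector<double> diagA(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = Ap[i]; k < Ap[i + 1]; ++k)
      if (Ai[k] == i) diagA[i] = Ax[k];

  double sigma2_a = prior_scale;
  NumericVector out_s2(n_keep), out_round(n_keep);
  int kept = 0;

  std::vector<double> xr(p), bm(p);

  for (int round = 1; round <= n_rounds; ++round) {
    if (use_likelihood) {
      // 1. latent liabilities
      for (int i = 0; i < n; ++i) {
        double m = xb[i] + u[i];
        l[i] = (y[i] == 1) ? rtnorm_pos(m) : -rtnorm_pos(-m);
        if (!R_finite(l[i]))
          stop("non-finite latent liability at round %d", round);
      }
      // 2. fixed effects: beta ~ N((X'X)^-1 X'(l-u), (X'X)^-1)
      for (int j = 0; j < p; ++j) xr[j] = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = l[i] - u[i];
        for (int j = 0; j < p; ++j) xr[j] += X(i, j) * r;
      }
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        for (int k = 0; k < p; ++k) s += XtXinv(j, k) * xr[k];
        bm[j] = s;
      }
      // beta = mean + Uchol %*% z, Uchol lower-triangular with
      // Uchol %*% t(Uchol) = (X'X)^-1
      {
        std::vector<double> z(p);
        for (int j = 0; j < p; ++j) z[j] = norm_rand();
        for (int j = 0; j < p; ++j) {
          double s = bm[j];
          for (int k = 0; k <= j; ++k) s += Uchol(j, k) * z[k];
          beta[j] = s;
        }
      }
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < p; ++j) s += X(i, j) * beta[j];
        xb[i] = s;
      }
    }
    // 3. breeding values, single-site
    double inv_s2 = 1.0 / sigma2_a;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = Ap[i]; k < Ap[i + 1]; ++k) {
        int j = Ai[k];
        if (j != i) s += Ax[k] * u[j];
      }
      double prec = (use_likelihood ? 1.0 : 0.0) + diagA[i] * inv_s2;
      double mean = ((use_likelihood ? (l[i] - xb[i]) : 0.0) - s * inv_s2)
        / prec;
      u[i] = mean + norm_rand() / std::sqrt(prec);
    }
    // 4. sigma2_a | u  ~ scaled-inv-chi2(prior_df + n, ...)
    double quad = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = Ap[i]; k < Ap[i + 1]; ++k) s += Ax[k] * u[Ai[k]];
      quad += u[i] * s;
    }
    double df_post = prior_df + n;
    double chi = R::rchisq(df_post);
    sigma2_a = (prior_df * prior_scale + quad) / chi;
    if (!R_finite(sigma2_a) || sigma2_a <= 0)
      stop("non-finite variance sample at round %d", round);

    if (round > burn_in && (round - burn_in) % thin == 0 && kept < n_keep) {
      out_s2[kept] = sigma2_a;
      out_round[kept] = round;
      ++kept;
    }
  }
  return List::create(Named("sigma2_a") = out_s2,
                      Named("round") = out_round);
}
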