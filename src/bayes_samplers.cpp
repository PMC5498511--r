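#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs samplers for the Bayes-C (common marker variance) and
// Bayes-B (locus-specific marker variance) mixture models:
//
//   y = 1*mu + sum_j x_j b_j d_j + e,   d_j ~ Bern(1 - pi),
//   Bayes-C: b_j ~ N(0, s2b)            with s2b ~ scaled-inv-chi2(nub, Sb)
//   Bayes-B: b_j ~ N(0, s2b_j), s2b_j ~ scaled-inv-chi2(nub, Sb)
//   e ~ N(0, I s2e),                    s2e ~ scaled-inv-chi2(nue, Se)
//
// X and y arrive centered. The running residual e = y - X*beta is kept in
// sync so each locus update costs two length-n dot products. Inclusion
// indicators are sampled from the marginal odds with the effect integrated
// out against its (locus-specific) normal prior. R's RNG is used
// throughout, so set.seed() in R makes chains reproducible.

static inline double rinvchisq(double df, double scale) {
  // draw from scaled-inv-chi2(df, scale) = df*scale / chi2_df
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export]]
List gibbs_bayes_mixture(const NumericMatrix& X, const NumericVector& y,
                         int n_iter, int burn_in, int thin,
                         double pi_zero, bool update_pi,
                         double pi_prior_counts, double pi_prior_probin,
                         double nub, double Sb, double nue, double Se,
                         bool locus_specific_variance,
                         bool update_scale, double scale_shape0) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector beta(p), s2b_j(p), e = clone(y);
  IntegerVector delta(p);
  std::vector<double> cxx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    cxx[j] = s;
    s2b_j[j] = Sb;  // prior-mode start for Bayes-B
  }
  double mu = 0.0, s2b = Sb, s2e = Se, pi = pi_zero;
  // Gamma prior on the slab scale, mode at the R2-heuristic Sb
  double S_cur = Sb;
  const double scale_rate0 = (scale_shape0 - 1.0) / Sb;

  NumericVector beta_sum(p), pip_sum(p);
  double mu_sum = 0, s2b_sum = 0, s2e_sum = 0, pi_sum = 0;
  int n_kept = 0;

  GetRNGstate();
  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar = (ebar + n * mu) / n;
    double mu_new = ebar + ::norm_rand() * std::sqrt(s2e / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // locus effects and indicators
    int m_in = 0;
    double ss_b = 0.0;
    const double* xbase = &X(0, 0);
    double* ep = &e[0];
    for (int j = 0; j < p; ++j) {
      const double cj = cxx[j];
      if (cj <= 0.0) { beta[j] = 0.0; delta[j] = 0; continue; }
      const double* xj = xbase + (size_t)j * n;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * ep[i];
      rhs += cj * beta[j];
      const double vb = locus_specific_variance ? s2b_j[j] : s2b;
      const double denom = cj * vb + s2e;
      const double log_odds_in = std::log((1.0 - pi) / pi)
        + 0.5 * (std::log(s2e) - std::log(denom))
        + 0.5 * rhs * rhs * vb / (s2e * denom);
      const double p_in = 1.0 / (1.0 + std::exp(-log_odds_in));
      const double b_old = beta[j];
      if (::unif_rand() < p_in) {
        const double prec = cj + s2e / vb;
        const double b_new = rhs / prec + ::norm_rand() * std::sqrt(s2e / prec);
        if (b_new != b_old) {
          const double diff = b_old - b_new;
          for (int i = 0; i < n; ++i) ep[i] += xj[i] * diff;
        }
        beta[j] = b_new;
        delta[j] = 1;
        ++m_in;
        ss_b += b_new * b_new;
        if (locus_specific_variance) {
          s2b_j[j] = rinvchisq(nub + 1.0, (b_new * b_new + nub * S_cur) / (nub + 1.0));
        }
      } else {
        if (b_old != 0.0) {
          for (int i = 0; i < n; ++i) ep[i] += xj[i] * b_old;
        }
        beta[j] = 0.0;
        delta[j] = 0;
        if (locus_specific_variance) {
          s2b_j[j] = rinvchisq(nub, S_cur);  // refresh from the prior
        }
      }
    }

    // variance components
    if (!locus_specific_variance) {
      s2b = rinvchisq(nub + m_in, (ss_b + nub * Sb) / (nub + m_in));
    } else {
      // report the mean of locus variances as the marker-variance summary
      s2b = mean(s2b_j);
    }
    if (locus_specific_variance && update_scale) {
      // conjugate Gamma update of the common slab scale given all locus
      // variances (each scaled-inv-chi2(nub, S))
      double sum_inv = 0.0;
      for (int j = 0; j < p; ++j) sum_inv += 1.0 / s2b_j[j];
      const double shape = scale_shape0 + 0.5 * p * nub;
      const double rate = scale_rate0 + 0.5 * nub * sum_inv;
      S_cur = R::rgamma(shape, 1.0 / rate);
    }
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = rinvchisq(nue + n, (sse + nue * Se) / (nue + n));

    if (update_pi) {
      // pi is the zero-mass probability; Beta prior parameterised by
      // prior counts and prior inclusion probability
      const double a = (p - m_in) + pi_prior_counts * (1.0 - pi_prior_probin);
      const double b = m_in + pi_prior_counts * pi_prior_probin;
      pi = R::rbeta(a, b);
      if (pi < 1e-8) pi = 1e-8;
      if (pi > 1.0 - 1e-8) pi = 1.0 - 1e-8;
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      for (int j = 0; j < p; ++j) {
        beta_sum[j] += beta[j];
        pip_sum[j] += delta[j];
      }
      mu_sum += mu; s2b_sum += s2b; s2e_sum += s2e; pi_sum += pi;
    }
  }
  PutRNGstate();

  NumericVector beta_mean(p), pip(p);
  for (int j = 0; j < p; ++j) {
    beta_mean[j] = beta_sum[j] / n_kept;
    pip[j] = pip_sum[j] / n_kept;
  }
  return List::create(
    _["effects"] = beta_mean,
    _["inclusion_prob"] = pip,
    _["intercept"] = mu_sum / n_kept,
    _["marker_variance"] = s2b_sum / n_kept,
    _["residual_variance"] = s2e_sum / n_kept,
    _["pi_zero"] = pi_sum / n_kept,
    _["n_kept"] = n_kept);
}
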