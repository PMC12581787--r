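// Gibbs samplers for the Bayes alphabet marker-effect models.
//   BayesA: every marker has an effect with its own variance
//           (scaled-inverse-chi-square prior -> scaled-t marginal).
//   BayesB: spike at zero with prior probability pi0, BayesA slab otherwise.
//   BayesC: spike at zero, common slab variance across markers.
// Fixed effects get flat priors; the residual variance a scaled-inverse-
// chi-square prior. Uses R's RNG, so results are reproducible via set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double rinvchisq(double df, double scale) {
  // scaled-inverse-chi-square(df, scale): df*scale / chisq(df)
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".bayes_gibbs")]]
List bayes_gibbs(NumericVector y, NumericMatrix X, NumericMatrix W,
                 int model, int n_iter, int burn_in, int thin,
                 double pi0, double nu_a, double scale_a,
                 double nu_e, double scale_e) {
  const int n = y.size(), q = X.ncol(), m = W.ncol();
  std::vector<double> beta(q, 0.0), a(m, 0.0), s2k(m, scale_a);
  std::vector<bool> incl(m, model == 0);  // BayesA: always included
  double s2a = scale_a;                   // common slab variance (BayesC)
  double s2e = scale_e;

  std::vector<double> xtx(q), wtw(m);
  for (int j = 0; j < q; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int k = 0; k < m; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, k) * W(i, k);
    wtw[k] = s;
  }

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];  // effects start at zero

  std::vector<double> a_sum(m, 0.0), incl_sum(m, 0.0), beta_sum(q, 0.0),
      g_sum(n, 0.0);
  double s2e_sum = 0.0, h2_sum = 0.0;
  int n_kept = 0;
  const double log_prior_odds = std::log((1.0 - pi0) / pi0);

  for (int it = 0; it < n_iter; ++it) {
    // fixed effects, flat prior
    for (int j = 0; j < q; ++j) {
      if (xtx[j] <= 0) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * (e[i] + X(i, j) * beta[j]);
      double mean = rhs / xtx[j];
      double bnew = R::rnorm(mean, std::sqrt(s2e / xtx[j]));
      double diff = bnew - beta[j];
      for (int i = 0; i < n; ++i) e[i] -= X(i, j) * diff;
      beta[j] = bnew;
    }

    int m_in = 0;
    double ssq_in = 0.0;
    for (int k = 0; k < m; ++k) {
      if (wtw[k] <= 0) { a[k] = 0.0; continue; }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += W(i, k) * e[i];
      rhs += wtw[k] * a[k];  // e excludes nothing; add back own contribution
      double vk = (model == 2) ? s2a : s2k[k];
      bool in = true;
      if (model != 0) {
        // Bayes factor for a nonzero effect from the sufficient statistic
        // rhs ~ N(0, wtw*s2e) under exclusion, N(0, wtw*s2e + wtw^2*vk)
        // under inclusion
        double v0 = wtw[k] * s2e;
        double v1 = v0 + wtw[k] * wtw[k] * vk;
        double log_bf = 0.5 * (std::log(v0) - std::log(v1)) +
                        0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
        double pr = 1.0 / (1.0 + std::exp(-(log_bf + log_prior_odds)));
        in = (unif_rand() < pr);
      }
      double anew = 0.0;
      if (in) {
        double C = wtw[k] + s2e / vk;
        anew = R::rnorm(rhs / C, std::sqrt(s2e / C));
      }
      double diff = anew - a[k];
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= W(i, k) * diff;
      a[k] = anew;
      incl[k] = in;
      if (in) { ++m_in; ssq_in += anew * anew; }
      if (model == 0) {
        s2k[k] = rinvchisq(nu_a + 1.0, (nu_a * scale_a + a[k] * a[k]) / (nu_a + 1.0));
      } else if (model == 1) {
        double ss = in ? a[k] * a[k] : 0.0;
        double df = nu_a + (in ? 1.0 : 0.0);
        s2k[k] = rinvchisq(df, (nu_a * scale_a + ss) / df);
      }
    }
    if (model == 2) {
      double df = nu_a + m_in;
      s2a = rinvchisq(df, (nu_a * scale_a + ssq_in) / df);
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = rinvchisq(nu_e + n, (nu_e * scale_e + sse) / (nu_e + n));

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      double gm = 0.0, gss = 0.0;
      for (int i = 0; i < n; ++i) {
        double xb = 0.0;
        for (int j = 0; j < q; ++j) xb += X(i, j) * beta[j];
        double g = y[i] - xb - e[i];  // = W a for this draw
        g_sum[i] += g;
        gm += g;
        gss += g * g;
      }
      gm /= n;
      double vg = gss / n - gm * gm;
      h2_sum += vg / (vg + s2e);
      s2e_sum += s2e;
      for (int k = 0; k < m; ++k) {
        a_sum[k] += a[k];
        incl_sum[k] += incl[k] ? 1.0 : 0.0;
      }
      for (int j = 0; j < q; ++j) beta_sum[j] += beta[j];
    }
  }

  NumericVector a_hat(m), inclusion(m), beta_hat(q), g_hat(n);
  for (int k = 0; k < m; ++k) {
    a_hat[k] = a_sum[k] / n_kept;
    inclusion[k] = incl_sum[k] / n_kept;
  }
  for (int j = 0; j < q; ++j) beta_hat[j] = beta_sum[j] / n_kept;
  for (int i = 0; i < n; ++i) g_hat[i] = g_sum[i] / n_kept;
  return List::create(_["a"] = a_hat, _["inclusion"] = inclusion,
                      _["beta"] = beta_hat, _["g"] = g_hat,
                      _["sigma_e2"] = s2e_sum / n_kept,
                      _["h2"] = h2_sum / n_kept, _["n_kept"] = n_kept);
}
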