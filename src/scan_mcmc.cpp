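// Reversible-jump MCMC for the multinomial-Dirichlet F_ST outlier model.
//
// Locus-by-population differentiation is decomposed on the logit scale as
// logit(Fst_ij) = alpha_i + beta_j. Population allele frequencies follow a
// beta distribution around the ancestral frequency p_i with precision
// theta_ij = (1 - Fst_ij)/Fst_ij and are integrated out, leaving a
// beta-binomial likelihood for the observed allele counts. A reversible
// jump toggles the locus effect alpha_i in and out of the model with a
// configurable prior odds for the neutral (alpha excluded) model; the
// posterior inclusion probability per locus is the scan's primary output.
// Uses the R RNG, so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double logit_inv(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// beta-binomial log-likelihood of counts (a alt of n) for one locus x pop
static inline double ll_cell(double a, double n, double p, double f) {
  const double eps = 1e-9;
  if (f < eps) f = eps;
  if (f > 1.0 - eps) f = 1.0 - eps;
  double th = (1.0 - f) / f;
  return R::lgammafn(th) - R::lgammafn(th + n) +
         R::lgammafn(th * p + a) - R::lgammafn(th * p) +
         R::lgammafn(th * (1.0 - p) + n - a) - R::lgammafn(th * (1.0 - p));
}

struct ScanState {
  const NumericMatrix& alt, & tot;
  int L, P;
  std::vector<double> p, alpha, beta;
  std::vector<bool> incl;
  std::vector<double> cell;   // L x P cached cell log-likelihoods
  std::vector<double> ll;     // per-locus row sums

  ScanState(const NumericMatrix& a, const NumericMatrix& t)
    : alt(a), tot(t), L(a.nrow()), P(a.ncol()),
      p(L), alpha(L, 0.0), beta(P, 0.0), incl(L, true),
      cell(static_cast<size_t>(L) * P), ll(L) {}

  double eval_row(int i, double p_i, double a_i, double* out) const {
    double s = 0.0;
    for (int j = 0; j < P; ++j) {
      double f = logit_inv(a_i + beta[j]);
      double v = ll_cell(alt(i, j), tot(i, j), p_i, f);
      if (out) out[j] = v;
      s += v;
    }
    return s;
  }

  void refresh_row(int i) {
    ll[i] = eval_row(i, p[i], incl[i] ? alpha[i] : 0.0, &cell[i * (size_t)P]);
  }

  void refresh_all() { for (int i = 0; i < L; ++i) refresh_row(i); }
};

// [[Rcpp::export]]
List scan_mcmc_cpp(NumericMatrix alt, NumericMatrix tot,
                   double prior_odds,
                   int n_burn, int n_keep, int thin,
                   int n_pilot,
                   double sd_alpha_prior, double mu_beta_prior,
                   double sd_beta_prior,
                   double prop_p, double prop_alpha, double prop_beta) {
  RNGScope scope;
  ScanState st(alt, tot);
  const int L = st.L, P = st.P;
  const double log_prior_incl = -std::log1p(prior_odds);        // log P(incl)
  const double log_prior_excl = std::log(prior_odds) - std::log1p(prior_odds);

  for (int i = 0; i < L; ++i) {
    double tots = 0.0, alts = 0.0;
    for (int j = 0; j < P; ++j) { tots += tot(i, j); alts += alt(i, j); }
    st.p[i] = std::min(0.99, std::max(0.01, alts / std::max(tots, 1.0)));
  }
  for (int j = 0; j < P; ++j) st.beta[j] = mu_beta_prior;
  st.refresh_all();

  std::vector<double> rownew(P);

  auto update_p = [&](int i) {
    double cur_a = st.incl[i] ? st.alpha[i] : 0.0;
    double pn = st.p[i] + R::runif(-prop_p, prop_p);
    if (pn <= 0.0 || pn >= 1.0) return;
    double lln = st.eval_row(i, pn, cur_a, rownew.data());
    if (std::log(R::runif(0, 1)) < lln - st.ll[i]) {
      st.p[i] = pn; st.ll[i] = lln;
      std::copy(rownew.begin(), rownew.end(), st.cell.begin() + i * (size_t)P);
    }
  };

  auto update_alpha = [&](int i) {
    if (!st.incl[i]) return;
    double an = st.alpha[i] + R::rnorm(0.0, prop_alpha);
    double lln = st.eval_row(i, st.p[i], an, rownew.data());
    double lr = lln - st.ll[i] +
      R::dnorm(an, 0.0, sd_alpha_prior, 1) -
      R::dnorm(st.alpha[i], 0.0, sd_alpha_prior, 1);
    if (std::log(R::runif(0, 1)) < lr) {
      st.alpha[i] = an; st.ll[i] = lln;
      std::copy(rownew.begin(), rownew.end(), st.cell.begin() + i * (size_t)P);
    }
  };

  auto update_beta = [&](void) {
    for (int j = 0; j < P; ++j) {
      double bn = st.beta[j] + R::rnorm(0.0, prop_beta);
      double delta = 0.0;
      std::vector<double> newcol(L);
      for (int i = 0; i < L; ++i) {
        double a_i = st.incl[i] ? st.alpha[i] : 0.0;
        double f = logit_inv(a_i + bn);
        newcol[i] = ll_cell(st.alt(i, j), st.tot(i, j), st.p[i], f);
        delta += newcol[i] - st.cell[i * (size_t)P + j];
      }
      double lr = delta +
        R::dnorm(bn, mu_beta_prior, sd_beta_prior, 1) -
        R::dnorm(st.beta[j], mu_beta_prior, sd_beta_prior, 1);
      if (std::log(R::runif(0, 1)) < lr) {
        st.beta[j] = bn;
        for (int i = 0; i < L; ++i) {
          st.ll[i] += newcol[i] - st.cell[i * (size_t)P + j];
          st.cell[i * (size_t)P + j] = newcol[i];
        }
      }
    }
  };

  // --- pilot phase: tune per-locus alpha proposal location/scale ----------
  NumericVector pilot_mean(L, 0.0), pilot_m2(L, 0.0);
  int pilot_n = 0;
  for (int it = 0; it < n_pilot; ++it) {
    for (int i = 0; i < L; ++i) { update_p(i); update_alpha(i); }
    update_beta();
    if (it >= n_pilot / 4) {
      ++pilot_n;
      for (int i = 0; i < L; ++i) {
        double d = st.alpha[i] - pilot_mean[i];
        pilot_mean[i] += d / pilot_n;
        pilot_m2[i] += d * (st.alpha[i] - pilot_mean[i]);
      }
    }
  }
  std::vector<double> prop_mu(L), prop_sd(L);
  for (int i = 0; i < L; ++i) {
    prop_mu[i] = pilot_mean[i];
    double v = pilot_n > 1 ? pilot_m2[i] / (pilot_n - 1) : 1.0;
    prop_sd[i] = std::max(0.05, std::sqrt(v) * 1.5);
  }

  // --- main phase: start from the all-neutral configuration ---------------
  for (int i = 0; i < L; ++i) st.incl[i] = false;
  st.refresh_all();

  NumericVector incl_sum(L, 0.0), incl_first(L, 0.0), incl_second(L, 0.0);
  NumericVector alpha_sum(L, 0.0), alpha_n(L, 0.0), fst_sum(L, 0.0);
  NumericVector beta_mean(P, 0.0);
  int kept = 0, kept_first = 0, kept_second = 0;
  const int n_iter = n_burn + n_keep;

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < L; ++i) {
      update_p(i);
      update_alpha(i);
      // reversible-jump toggle, birth proposal q_i = N(prop_mu, prop_sd)
      if (!st.incl[i]) {
        double an = R::rnorm(prop_mu[i], prop_sd[i]);
        double lln = st.eval_row(i, st.p[i], an, rownew.data());
        double lr = lln - st.ll[i] + log_prior_incl - log_prior_excl +
          R::dnorm(an, 0.0, sd_alpha_prior, 1) -
          R::dnorm(an, prop_mu[i], prop_sd[i], 1);
        if (std::log(R::runif(0, 1)) < lr) {
          st.incl[i] = true; st.alpha[i] = an; st.ll[i] = lln;
          std::copy(rownew.begin(), rownew.end(),
                    st.cell.begin() + i * (size_t)P);
        }
      } else {
        double lln = st.eval_row(i, st.p[i], 0.0, rownew.data());
        double lr = lln - st.ll[i] + log_prior_excl - log_prior_incl +
          R::dnorm(st.alpha[i], prop_mu[i], prop_sd[i], 1) -
          R::dnorm(st.alpha[i], 0.0, sd_alpha_prior, 1);
        if (std::log(R::runif(0, 1)) < lr) {
          st.incl[i] = false; st.ll[i] = lln;
          std::copy(rownew.begin(), rownew.end(),
                    st.cell.begin() + i * (size_t)P);
        }
      }
    }
    update_beta();

    if (it >= n_burn && ((it - n_burn) % thin == 0)) {
      ++kept;
      bool first_half = (it - n_burn) < n_keep / 2;
      if (first_half) ++kept_first; else ++kept_second;
      for (int i = 0; i < L; ++i) {
        double a_cur = st.incl[i] ? st.alpha[i] : 0.0;
        if (st.incl[i]) {
          incl_sum[i] += 1.0;
          alpha_sum[i] += st.alpha[i];
          alpha_n[i] += 1.0;
          if (first_half) incl_first[i] += 1.0; else incl_second[i] += 1.0;
        }
        double f = 0.0;
        for (int j = 0; j < P; ++j) f += logit_inv(a_cur + st.beta[j]);
        fst_sum[i] += f / P;
      }
      for (int j = 0; j < P; ++j) beta_mean[j] += st.beta[j];
    }
  }

  NumericVector prob(L), fst(L), alpha_mean(L), prob_first(L), prob_second(L);
  for (int i = 0; i < L; ++i) {
    prob[i] = incl_sum[i] / kept;
    fst[i] = fst_sum[i] / kept;
    alpha_mean[i] = alpha_n[i] > 0 ? alpha_sum[i] / alpha_n[i] : 0.0;
    prob_first[i] = kept_first > 0 ? incl_first[i] / kept_first : NA_REAL;
    prob_second[i] = kept_second > 0 ? incl_second[i] / kept_second : NA_REAL;
  }
  for (int j = 0; j < P; ++j) beta_mean[j] /= kept;

  return List::create(
    _["prob"] = prob, _["fst"] = fst, _["alpha"] = alpha_mean,
    _["beta"] = beta_mean, _["n_samples"] = kept,
    _["prob_first_half"] = prob_first, _["prob_second_half"] = prob_second);
}
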