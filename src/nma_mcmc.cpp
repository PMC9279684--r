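#include <Rcpp.h>
using namespace Rcpp;

// Arm-based binomial-logit network meta-analysis sampler.
//
// Model: r_a ~ Binomial(n_a, p_a), logit(p_a) = mu_{trial(a)} + delta_a,
// delta = 0 on the baseline arm of each trial (the arm whose treatment has
// the lowest index; index 0 is the network reference). Fixed effects:
// delta_a = d[trt_a] - d[baseline_trt]. Random effects: delta_a ~
// Normal(d[trt_a] - d[baseline_trt], tau^2), independently per non-baseline
// arm (baseline-arm parameterisation; the fitted networks are two-arm).
//
// Sampling is adaptive random-walk Metropolis-within-Gibbs: one univariate
// normal proposal per parameter per sweep, with per-parameter log step
// sizes adapted toward ~35% acceptance during burn-in only and frozen
// afterwards, preserving detailed balance in the retained draws.
// Randomness comes from R's RNG stream, so R-level set.seed() governs the
// chain completely.

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// binomial log-likelihood of one arm up to a data-only constant
static inline double arm_ll(double r, double n, double lp) {
  return r * lp - n * log1pexp_(lp);
}

// residual deviance contribution of one arm (WinBUGS convention)
static inline double arm_dev(double r, double n, double p) {
  double rhat = n * p;
  double dev = 0.0;
  if (r > 0) dev += r * std::log(r / rhat);
  if (n - r > 0) dev += (n - r) * std::log((n - r) / (n - rhat));
  return 2.0 * dev;
}

// [[Rcpp::export(name = ".nma_mcmc_chain")]]
List nma_mcmc_chain(IntegerVector trial, IntegerVector trt,
                    IntegerVector r, IntegerVector n,
                    int n_trt, int n_trial, bool random,
                    double prior_mu_sd, double prior_d_sd, double tau_upper,
                    NumericVector tau_fixed,
                    int burn, int iters, int thin,
                    NumericVector init_d, NumericVector init_mu,
                    double init_tau) {
  const int A = trial.size();
  const bool fix_tau = tau_fixed.size() > 0;

  // baseline arm and baseline treatment per trial
  std::vector<int> base_arm(n_trial, -1), base_trt(n_trial, n_trt);
  for (int a = 0; a < A; ++a) {
    int i = trial[a];
    if (trt[a] < base_trt[i]) { base_trt[i] = trt[a]; base_arm[i] = a; }
  }
  std::vector<std::vector<int>> trial_arms(n_trial);
  for (int a = 0; a < A; ++a) trial_arms[trial[a]].push_back(a);
  // non-baseline arms affected by each d parameter
  std::vector<std::vector<int>> d_arms(n_trt);
  std::vector<int> free_arms;  // non-baseline arms
  for (int a = 0; a < A; ++a) {
    if (a == base_arm[trial[a]]) continue;
    free_arms.push_back(a);
    d_arms[trt[a]].push_back(a);
    int bt = base_trt[trial[a]];
    if (bt != trt[a]) d_arms[bt].push_back(a);
  }

  // state
  std::vector<double> mu(init_mu.begin(), init_mu.end());
  std::vector<double> d(init_d.begin(), init_d.end());
  double tau = fix_tau ? tau_fixed[0] : init_tau;
  std::vector<double> delta(A, 0.0);
  for (size_t k = 0; k < free_arms.size(); ++k) {
    int a = free_arms[k];
    delta[a] = d[trt[a]] - d[base_trt[trial[a]]];
  }

  // adaptive step sizes (log scale) and acceptance counters
  const int n_par = n_trial + (n_trt - 1) + (random ? (int)free_arms.size() : 0) +
                    (random && !fix_tau ? 1 : 0);
  std::vector<double> lstep(n_par, std::log(0.5));
  std::vector<double> acc(n_par, 0.0), tries(n_par, 0.0);

  const int total = burn + iters;
  const int nstore = iters / thin;
  NumericMatrix d_store(nstore, std::max(n_trt - 1, 0));
  NumericMatrix mu_store(nstore, n_trial);
  NumericVector tau_store(random ? nstore : 0);
  NumericVector dev_store(nstore);
  NumericVector psum(A);

  const double mu_prec = 1.0 / (prior_mu_sd * prior_mu_sd);
  const double d_prec = 1.0 / (prior_d_sd * prior_d_sd);

  RNGScope scope;
  int stored = 0;
  for (int it = 0; it < total; ++it) {
    const bool adapting = it < burn;
    const double gamma = adapting ? 1.0 / std::sqrt(1.0 + 0.1 * it) : 0.0;
    int pid = 0;

    // trial baselines mu_i
    for (int i = 0; i < n_trial; ++i, ++pid) {
      double step = std::exp(lstep[pid]);
      double prop = mu[i] + step * norm_rand();
      double la = -0.5 * mu_prec * (prop * prop - mu[i] * mu[i]);
      for (int a : trial_arms[i]) {
        la += arm_ll(r[a], n[a], prop + delta[a]) -
              arm_ll(r[a], n[a], mu[i] + delta[a]);
      }
      bool ok = std::log(unif_rand()) < la;
      if (ok) mu[i] = prop;
      if (adapting) lstep[pid] += gamma * ((ok ? 1.0 : 0.0) - 0.35);
      else { acc[pid] += ok; tries[pid] += 1.0; }
    }

    // basic parameters d_t (t >= 1; reference pinned at 0)
    for (int t = 1; t < n_trt; ++t, ++pid) {
      double step = std::exp(lstep[pid]);
      double prop = d[t] + step * norm_rand();
      double la = -0.5 * d_prec * (prop * prop - d[t] * d[t]);
      if (!random) {
        for (int a : d_arms[t]) {
          int bt = base_trt[trial[a]];
          double dn = (trt[a] == t ? prop : d[trt[a]]) -
                      (bt == t ? prop : d[bt]);
          la += arm_ll(r[a], n[a], mu[trial[a]] + dn) -
                arm_ll(r[a], n[a], mu[trial[a]] + delta[a]);
        }
      } else {
        double tp = 1.0 / (tau * tau);
        for (int a : d_arms[t]) {
          int bt = base_trt[trial[a]];
          double m_new = (trt[a] == t ? prop : d[trt[a]]) -
                         (bt == t ? prop : d[bt]);
          double m_old = d[trt[a]] - d[bt];
          double e_new = delta[a] - m_new, e_old = delta[a] - m_old;
          la += -0.5 * tp * (e_new * e_new - e_old * e_old);
        }
      }
      bool ok = std::log(unif_rand()) < la;
      if (ok) {
        d[t] = prop;
        if (!random) {
          for (int a : d_arms[t])
            delta[a] = d[trt[a]] - d[base_trt[trial[a]]];
        }
      }
      if (adapting) lstep[pid] += gamma * ((ok ? 1.0 : 0.0) - 0.35);
      else { acc[pid] += ok; tries[pid] += 1.0; }
    }

    // trial-specific effects delta_a (random-effects model only)
    if (random) {
      double tp = 1.0 / (tau * tau);
      for (int a : free_arms) {
        double step = std::exp(lstep[pid]);
        double prop = delta[a] + step * norm_rand();
        double m = d[trt[a]] - d[base_trt[trial[a]]];
        double e_new = prop - m, e_old = delta[a] - m;
        double la = -0.5 * tp * (e_new * e_new - e_old * e_old) +
                    arm_ll(r[a], n[a], mu[trial[a]] + prop) -
                    arm_ll(r[a], n[a], mu[trial[a]] + delta[a]);
        bool ok = std::log(unif_rand()) < la;
        if (ok) delta[a] = prop;
        if (adapting) lstep[pid] += gamma * ((ok ? 1.0 : 0.0) - 0.35);
        else { acc[pid] += ok; tries[pid] += 1.0; }
        ++pid;
      }
      // heterogeneity SD tau ~ Uniform(0, tau_upper)
      if (!fix_tau) {
        double step = std::exp(lstep[pid]);
        double prop = tau + step * norm_rand();
        bool ok = false;
        if (prop > 0.0 && prop < tau_upper) {
          double la = 0.0;
          for (int a : free_arms) {
            double m = d[trt[a]] - d[base_trt[trial[a]]];
            double e = delta[a] - m;
            la += -std::log(prop) - 0.5 * e * e / (prop * prop) +
                  std::log(tau) + 0.5 * e * e / (tau * tau);
          }
          ok = std::log(unif_rand()) < la;
        }
        if (ok) tau = prop;
        if (adapting) lstep[pid] += gamma * ((ok ? 1.0 : 0.0) - 0.35);
        else { acc[pid] += ok; tries[pid] += 1.0; }
        ++pid;
      }
    }

    // store thinned post-burn-in draws
    if (it >= burn && ((it - burn) % thin) == (thin - 1) && stored < nstore) {
      double dev = 0.0;
      for (int a = 0; a < A; ++a) {
        double p = 1.0 / (1.0 + std::exp(-(mu[trial[a]] + delta[a])));
        psum[a] += p;
        dev += arm_dev(r[a], n[a], p);
      }
      for (int t = 1; t < n_trt; ++t) d_store(stored, t - 1) = d[t];
      for (int i = 0; i < n_trial; ++i) mu_store(stored, i) = mu[i];
      if (random) tau_store[stored] = tau;
      dev_store[stored] = dev;
      ++stored;
    }
  }

  double acc_rate = NA_REAL;
  double tt = 0.0, ta = 0.0;
  for (int p = 0; p < n_par; ++p) { tt += tries[p]; ta += acc[p]; }
  if (tt > 0) acc_rate = ta / tt;

  return List::create(_["d"] = d_store, _["mu"] = mu_store,
                      _["tau"] = tau_store, _["deviance"] = dev_store,
                      _["psum"] = psum, _["n_stored"] = stored,
                      _["accept_rate"] = acc_rate);
}
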