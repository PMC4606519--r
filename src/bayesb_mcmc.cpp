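// Compiled MCMC core for the BayesB samplers.
//
// All randomness comes from R's RNG (unif_rand / R::rnorm / R::rchisq), so a
// chain is fully determined by set.seed() on the R side.  The pure-R
// reference kernels in R/kernels.R consume the RNG stream in exactly the
// same order; the test suite asserts lockstep agreement between the two
// implementations.
//
// Kernel kinds: 0 = single-site Gibbs, 1 = joint Gibbs, 2 = pseudo-prior
// Gibbs, 3 = Metropolis-Hastings (prior proposal), 4 = efficient MH
// (0.5 point-mass proposal).

#include <Rcpp.h>
#include <chrono>
using namespace Rcpp;

struct Pars {
  double pi, nu_b, s2_b, nu_e, s2_e;
  double ps2e, plam;        // pseudo-prior constants: sigma2_e~ and lambda~
  double mu0, tau2;         // optional proper normal prior for mu (tau2=Inf -> flat)
  int kind;
  int cycles;
  bool random_scan;
};

static inline double inv_logit(double t) {
  if (t > 0.0) return 1.0 / (1.0 + std::exp(-t));
  double e = std::exp(t);
  return e / (1.0 + e);
}

static inline double draw_scinv(double nu, double s2) {
  return nu * s2 / R::rchisq(nu);
}

// log density of the sufficient statistic X_j'w given the locus variance s
// (s = 0 gives the null-model density m0, s > 0 the slab density m1).
static inline double log_m(double rhs, double xtx, double s, double s2e) {
  double v = xtx * s2e + xtx * xtx * s;
  return R::dnorm(rhs, 0.0, std::sqrt(v), 1);
}

// inclusion probability on the logit scale, guarded at pi in {0, 1}
static inline double prob_delta1(double pi, double log_ratio) {
  if (pi <= 0.0) return 1.0;
  if (pi >= 1.0) return 0.0;
  return inv_logit(std::log((1.0 - pi) / pi) + log_ratio);
}

static void update_mu(int n, const Pars& P, double& mu, double s2e,
                      std::vector<double>& res) {
  double rsum = 0.0;
  for (int i = 0; i < n; ++i) rsum += res[i];
  double em = rsum / n + mu;  // mean of e_mu = y - X alpha
  double m, v;
  if (!R_FINITE(P.tau2)) {
    m = em; v = s2e / n;
  } else {
    double prec = n / s2e + 1.0 / P.tau2;
    m = (n * em / s2e + P.mu0 / P.tau2) / prec;
    v = 1.0 / prec;
  }
  double mu_new = R::rnorm(m, std::sqrt(v));
  double dmu = mu_new - mu;
  for (int i = 0; i < n; ++i) res[i] -= dmu;
  mu = mu_new;
}

static void update_sigma2_e(int n, const Pars& P, double& s2e,
                            const std::vector<double>& res) {
  double ee = 0.0;
  for (int i = 0; i < n; ++i) ee += res[i] * res[i];
  s2e = (P.nu_e * P.s2_e + ee) / R::rchisq(P.nu_e + n);
}

// One locus visit. beta/delta/s2j/res updated in place.
static void update_locus(const double* xj, double xtxj, bool mono, int n,
                         const Pars& P, std::vector<double>& beta,
                         std::vector<int>& delta, std::vector<double>& s2j,
                         double s2e, std::vector<double>& res, int j) {
  if (mono) {
    // monomorphic marker: delta pinned to 0; Gibbs kinds refresh beta and
    // sigma2_j from their priors, MH kinds skip entirely
    if (P.kind <= 2) {
      s2j[j] = draw_scinv(P.nu_b, P.s2_b);
      beta[j] = R::rnorm(0.0, std::sqrt(s2j[j]));
      delta[j] = 0;
    }
    return;
  }

  double a_old = delta[j] ? beta[j] : 0.0;
  double dot = 0.0;
  for (int i = 0; i < n; ++i) dot += xj[i] * res[i];
  double rhs = dot + xtxj * a_old;  // X_j'w without materialising w

  int d_new = 0;
  double b_new = 0.0;

  if (P.kind == 0 || P.kind == 1 || P.kind == 2) {
    double p1;
    if (P.kind == 0) {
      // likelihood ratio r = (beta*rhs - beta^2*xtx/2)/s2e; w'w cancels
      double r = (beta[j] * rhs - 0.5 * beta[j] * beta[j] * xtxj) / s2e;
      p1 = prob_delta1(P.pi, r);
    } else if (P.kind == 1) {
      double dlm = log_m(rhs, xtxj, s2j[j], s2e) - log_m(rhs, xtxj, 0.0, s2e);
      p1 = prob_delta1(P.pi, dlm);
    } else {
      double pm = rhs / (xtxj + P.plam);
      double pv = P.ps2e / (xtxj + P.plam);
      double r = (beta[j] * rhs - 0.5 * beta[j] * beta[j] * xtxj) / s2e;
      double lf1 = R::dnorm(beta[j], 0.0, std::sqrt(s2j[j]), 1);
      double lf0 = R::dnorm(beta[j], pm, std::sqrt(pv), 1);
      p1 = prob_delta1(P.pi, r + lf1 - lf0);
    }
    d_new = (unif_rand() < p1) ? 1 : 0;

    if (d_new) {
      double c = xtxj + s2e / s2j[j];
      b_new = R::rnorm(rhs / c, std::sqrt(s2e / c));
    } else if (P.kind == 2) {
      // pseudo-prior draw (does not touch the residual since alpha = 0)
      double pm = rhs / (xtxj + P.plam);
      double pv = P.ps2e / (xtxj + P.plam);
      b_new = R::rnorm(pm, std::sqrt(pv));
    } else {
      b_new = R::rnorm(0.0, std::sqrt(s2j[j]));
    }

    if (P.kind == 2 && d_new == 0) {
      s2j[j] = draw_scinv(P.nu_b, P.s2_b);  // prior draw
    } else {
      s2j[j] = (P.nu_b * P.s2_b + b_new * b_new) / R::rchisq(P.nu_b + 1.0);
    }
  } else {
    // Metropolis-Hastings kinds: state is the locus variance, 0 meaning the
    // point-mass (excluded) state
    double s_cur = delta[j] ? s2j[j] : 0.0;
    double lw_cur = log_m(rhs, xtxj, s_cur, s2e);
    if (P.kind == 4)
      lw_cur += (s_cur > 0.0) ? std::log1p(-P.pi) : std::log(P.pi);

    for (int c = 0; c < P.cycles; ++c) {
      double u = unif_rand();
      double zero_p = (P.kind == 3) ? P.pi : 0.5;
      double s_prop = (u < zero_p) ? 0.0 : draw_scinv(P.nu_b, P.s2_b);
      double lw_prop = log_m(rhs, xtxj, s_prop, s2e);
      if (P.kind == 4)
        lw_prop += (s_prop > 0.0) ? std::log1p(-P.pi) : std::log(P.pi);
      double u2 = unif_rand();  // always consumed, for RNG lockstep
      bool accept;
      if (lw_cur == R_NegInf) accept = (lw_prop > R_NegInf);
      else if (lw_prop == R_NegInf) accept = false;
      else accept = (std::log(u2) < lw_prop - lw_cur);
      if (accept) { s_cur = s_prop; lw_cur = lw_prop; }
    }

    if (s_cur > 0.0) {
      double c = xtxj + s2e / s_cur;
      b_new = R::rnorm(rhs / c, std::sqrt(s2e / c));
      d_new = 1;
      s2j[j] = s_cur;
    } else {
      b_new = 0.0;
      d_new = 0;
      s2j[j] = 0.0;
    }
  }

  double a_new = d_new ? b_new : 0.0;
  double da = a_new - a_old;
  if (da != 0.0) for (int i = 0; i < n; ++i) res[i] -= xj[i] * da;
  beta[j] = b_new;
  delta[j] = d_new;
}

// Fisher-Yates permutation of 0..k-1 driven by unif_rand(), mirrored in the
// reference implementation for random-scan lockstep.
static void scan_order(int k, bool random, std::vector<int>& ord) {
  for (int i = 0; i < k; ++i) ord[i] = i;
  if (!random) return;
  for (int i = k - 1; i >= 1; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

static void do_sweep(const NumericMatrix& X, const NumericVector& xtx,
                     const LogicalVector& mono, const Pars& P, double& mu,
                     std::vector<double>& beta, std::vector<int>& delta,
                     std::vector<double>& s2j, double& s2e,
                     std::vector<double>& res, std::vector<int>& ord) {
  int n = X.nrow(), k = X.ncol();
  update_mu(n, P, mu, s2e, res);
  scan_order(k, P.random_scan, ord);
  for (int jj = 0; jj < k; ++jj) {
    int j = ord[jj];
    update_locus(&X(0, j), xtx[j], mono[j], n, P, beta, delta, s2j, s2e,
                 res, j);
  }
  update_sigma2_e(n, P, s2e, res);
}

static double rebuild(const NumericMatrix& X, const NumericVector& y,
                      double mu, const std::vector<double>& beta,
                      const std::vector<int>& delta,
                      std::vector<double>& res) {
  int n = X.nrow(), k = X.ncol();
  std::vector<double> fresh(n);
  for (int i = 0; i < n; ++i) fresh[i] = y[i] - mu;
  for (int j = 0; j < k; ++j) {
    double a = delta[j] ? beta[j] : 0.0;
    if (a == 0.0) continue;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) fresh[i] -= xj[i] * a;
  }
  double drift = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(fresh[i] - res[i]);
    if (d > drift) drift = d;
    res[i] = fresh[i];
  }
  return drift;
}

static Pars make_pars(List hyper, int kind, int cycles, bool random_scan) {
  Pars P;
  P.pi   = as<double>(hyper["pi"]);
  P.nu_b = as<double>(hyper["nu_beta"]);
  P.s2_b = as<double>(hyper["s2_beta"]);
  P.nu_e = as<double>(hyper["nu_e"]);
  P.s2_e = as<double>(hyper["s2_e"]);
  RObject ps2e = hyper["pseudo_sigma2_e"];
  RObject plam = hyper["pseudo_lambda"];
  P.ps2e = ps2e.isNULL() ? NA_REAL : as<double>(ps2e);
  P.plam = plam.isNULL() ? NA_REAL : as<double>(plam);
  P.mu0  = as<double>(hyper["mu0"]);
  P.tau2 = as<double>(hyper["tau2"]);
  P.kind = kind;
  P.cycles = cycles;
  P.random_scan = random_scan;
  return P;
}

// [[Rcpp::export(name = ".cpp_run_chain")]]
List cpp_run_chain(NumericMatrix X, NumericVector y, NumericVector xtx,
                   LogicalVector mono, List hyper, int kind, int cycles,
                   int n_iter, int burn_in, int thin, bool random_scan,
                   double mu_init, NumericVector beta_init,
                   IntegerVector delta_init, NumericVector s2j_init,
                   double s2e_init, int rebuild_every) {
  int n = X.nrow(), k = X.ncol();
  Pars P = make_pars(hyper, kind, cycles, random_scan);

  double mu = mu_init, s2e = s2e_init;
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<int> delta(delta_init.begin(), delta_init.end());
  std::vector<double> s2j(s2j_init.begin(), s2j_init.end());
  std::vector<double> res(n);
  std::vector<int> ord(k);
  for (int i = 0; i < n; ++i) res[i] = y[i] - mu;
  for (int j = 0; j < k; ++j) {
    double a = delta[j] ? beta[j] : 0.0;
    if (a == 0.0) continue;
    for (int i = 0; i < n; ++i) res[i] -= X(i, j) * a;
  }

  int n_store = (n_iter - burn_in) / thin;
  NumericVector mu_st(n_store), s2e_st(n_store);
  NumericMatrix alpha_st(n_store, k);
  NumericVector dfreq(k);
  IntegerVector iter_st(n_store);
  double max_drift = 0.0;

  auto t0 = std::chrono::steady_clock::now();
  int s = 0;
  for (int it = 1; it <= n_iter; ++it) {
    do_sweep(X, xtx, mono, P, mu, beta, delta, s2j, s2e, res, ord);
    if (rebuild_every > 0 && it % rebuild_every == 0) {
      double d = rebuild(X, y, mu, beta, delta, res);
      if (d > max_drift) max_drift = d;
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && s < n_store) {
      mu_st[s] = mu;
      s2e_st[s] = s2e;
      iter_st[s] = it;
      for (int j = 0; j < k; ++j) {
        double a = delta[j] ? beta[j] : 0.0;
        alpha_st(s, j) = a;
        if (delta[j]) dfreq[j] += 1.0;
      }
      ++s;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  auto t1 = std::chrono::steady_clock::now();
  double secs = std::chrono::duration<double>(t1 - t0).count();
  if (n_store > 0) for (int j = 0; j < k; ++j) dfreq[j] /= n_store;

  return List::create(
      _["mu"] = mu_st, _["sigma2_e"] = s2e_st, _["alpha"] = alpha_st,
      _["delta_freq"] = dfreq, _["iterations"] = iter_st,
      _["wall_seconds"] = secs, _["max_drift"] = max_drift,
      _["final"] = List::create(
          _["mu"] = mu, _["beta"] = NumericVector(beta.begin(), beta.end()),
          _["delta"] = IntegerVector(delta.begin(), delta.end()),
          _["sigma2_j"] = NumericVector(s2j.begin(), s2j.end()),
          _["sigma2_e"] = s2e,
          _["residual"] = NumericVector(res.begin(), res.end())));
}

// One full sweep from a given state; the residual is rebuilt from y on
// entry, so the caller may have regenerated y (Geweke-style successive-
// conditional simulation).
// [[Rcpp::export(name = ".cpp_sweep")]]
List cpp_sweep(NumericMatrix X, NumericVector y, NumericVector xtx,
               LogicalVector mono, List hyper, int kind, int cycles,
               bool random_scan, double mu, NumericVector beta_,
               IntegerVector delta_, NumericVector s2j_, double s2e) {
  int n = X.nrow(), k = X.ncol();
  Pars P = make_pars(hyper, kind, cycles, random_scan);
  std::vector<double> beta(beta_.begin(), beta_.end());
  std::vector<int> delta(delta_.begin(), delta_.end());
  std::vector<double> s2j(s2j_.begin(), s2j_.end());
  std::vector<double> res(n);
  std::vector<int> ord(k);
  for (int i = 0; i < n; ++i) res[i] = y[i] - mu;
  for (int j = 0; j < k; ++j) {
    double a = delta[j] ? beta[j] : 0.0;
    if (a == 0.0) continue;
    for (int i = 0; i < n; ++i) res[i] -= X(i, j) * a;
  }
  do_sweep(X, xtx, mono, P, mu, beta, delta, s2j, s2e, res, ord);
  return List::create(
      _["mu"] = mu, _["beta"] = NumericVector(beta.begin(), beta.end()),
      _["delta"] = IntegerVector(delta.begin(), delta.end()),
      _["sigma2_j"] = NumericVector(s2j.begin(), s2j.end()),
      _["sigma2_e"] = s2e,
      _["residual"] = NumericVector(res.begin(), res.end()));
}
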