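#include <Rcpp.h>
using namespace Rcpp;

// log-factorial cache, grown on demand; avoids lgamma() in the inner loop
static std::vector<double> lgam_cache(1, 0.0);

static inline double lgam(int n) { // lgamma(n + 1)
  if ((size_t)n >= lgam_cache.size()) {
    size_t old = lgam_cache.size();
    lgam_cache.resize(n + 1);
    for (size_t k = old; k <= (size_t)n; ++k)
      lgam_cache[k] = lgam_cache[k - 1] + std::log((double)k);
  }
  return lgam_cache[n];
}

// Marginalized site log-likelihood:
//   log sum_{N = max(c)}^{K} Poisson(N | lambda) * prod_j Binomial(c_j | N, p_j)
// K < 0 requests the adaptive truncation (Poisson tail mass < ~1e-8).
static double site_loglik(const int* counts, int J, double loglam,
                          const double* p, int K) {
  double lam = std::exp(loglam);
  if (!R_finite(lam) || lam <= 0.0 || loglam > 25.0) return R_NegInf;
  int cmax = 0;
  for (int j = 0; j < J; ++j) if (counts[j] > cmax) cmax = counts[j];
  bool adaptive = K < 0;
  if (adaptive) {
    // generous cap; the relative-tail early stops below end the sums sooner
    K = (int)std::ceil(lam + 12.0 * std::sqrt(lam + 10.0) + 50.0);
    if (K > 2000000) return R_NegInf; // reject absurd abundance proposals
  }
  if (K < cmax) K = cmax; // never truncate below the data

  double Q = 1.0; // prod_j (1 - p_j): survival of the binomial thinning
  for (int j = 0; j < J; ++j) {
    int c = counts[j];
    if (p[j] >= 1.0) {
      if (c != cmax) return R_NegInf; // perfect detection pins N to c
      Q = 0.0;
    } else if (p[j] <= 0.0) {
      if (c != 0) return R_NegInf; // Binomial(c | N, 0) = 0 unless c = 0
    } else {
      Q *= 1.0 - p[j];
    }
  }

  // Terms are unimodal in N with mode near max(cmax, lam * Q); anchor the
  // sum there and walk outward, so the cost is O(sqrt(lam)) not O(lam).
  int N0 = (int)(lam * Q);
  if (N0 < cmax) N0 = cmax;
  if (N0 > K) N0 = K;

  double t0 = N0 * loglam - lam - lgam(N0);
  for (int j = 0; j < J; ++j) {
    int c = counts[j];
    if (p[j] > 0.0 && p[j] < 1.0) {
      t0 += lgam(N0) - lgam(c) - lgam(N0 - c)
          + c * std::log(p[j]) + (N0 - c) * std::log1p(-p[j]);
    }
  }
  if (!R_finite(t0)) return R_NegInf;

  // ratio term(N)/term(N-1) = lam * Q * N^(J'-1) / prod_j (N - c_j)
  auto step_ratio = [&](int N) {
    double r = lam * Q / N;
    for (int j = 0; j < J; ++j)
      if (p[j] > 0.0 && p[j] < 1.0) r *= (double)N / (N - counts[j]);
    return r;
  };

  double sum = 1.0, logscale = 0.0, rel = 1.0;
  for (int N = N0 + 1; N <= K; ++N) { // upward from the mode
    rel *= step_ratio(N);
    if (rel == 0.0) break;
    sum += rel;
    if (adaptive && rel < sum * 1e-13) break;
    if (sum > 1e250) { logscale += std::log(sum); rel /= sum; sum = 1.0; }
  }
  rel = 1.0;
  double down = 0.0;
  for (int N = N0; N > cmax; --N) { // downward from the mode
    double r = step_ratio(N);
    if (r <= 0.0) break;
    rel /= r;
    down += rel;
    if (adaptive && rel < (sum + down) * 1e-13) break;
  }
  return t0 + logscale + std::log(sum + down / std::exp(logscale));
}

// [[Rcpp::export]]
double nmix_site_loglik_cpp(IntegerVector counts, double lambda,
                            NumericVector p, int K) {
  int J = counts.size();
  std::vector<int> c(J);
  for (int j = 0; j < J; ++j) c[j] = counts[j];
  return site_loglik(c.data(), J, std::log(lambda), REAL(p), K);
}

struct LikState {
  int I, J, pab, qdet;
  const int* counts;      // I x J, column-major from R -> index i + I*j
  const double* X;        // I x pab
  const double* W;        // (I*J) x qdet, rows site-major: (i*J + j)
  const double* offset;   // length I
  std::vector<double> loglam, pmat, sll; // caches
};

static void update_loglam(LikState& st, const std::vector<double>& beta,
                          const std::vector<double>& eps) {
  for (int i = 0; i < st.I; ++i) {
    double v = st.offset[i] + eps[i];
    for (int k = 0; k < st.pab; ++k) v += st.X[i + st.I * k] * beta[k];
    st.loglam[i] = v;
  }
}

static void update_p(LikState& st, const std::vector<double>& alpha) {
  int IJ = st.I * st.J;
  for (int r = 0; r < IJ; ++r) {
    double v = 0.0;
    for (int k = 0; k < st.qdet; ++k) v += st.W[r + IJ * k] * alpha[k];
    st.pmat[r] = 1.0 / (1.0 + std::exp(-v));
  }
}

static double site_ll_cached(const LikState& st, int i) {
  std::vector<int> c(st.J);
  std::vector<double> p(st.J);
  for (int j = 0; j < st.J; ++j) {
    c[j] = st.counts[i + st.I * j];
    p[j] = st.pmat[i * st.J + j];
  }
  return site_loglik(c.data(), st.J, st.loglam[i], p.data(), -1);
}

static double full_ll(LikState& st) {
  double tot = 0.0;
  for (int i = 0; i < st.I; ++i) {
    st.sll[i] = site_ll_cached(st, i);
    if (st.sll[i] == R_NegInf) return R_NegInf;
    tot += st.sll[i];
  }
  return tot;
}

static inline double dnorm0(double x, double sd) {
  return -0.5 * std::log(2.0 * M_PI) - std::log(sd) - 0.5 * x * x / (sd * sd);
}

// Adaptive Metropolis-within-Gibbs for the marginalized N-mixture model.
// Blocks: coefficients (alpha+beta jointly, or beta alone with alpha fixed),
// each site random effect, log(sigma_eps). Proposal covariance for the
// coefficient block adapts Haario-style during burn-in only.
// [[Rcpp::export]]
List nmix_mcmc_cpp(IntegerMatrix counts, NumericMatrix X, NumericMatrix W,
                   NumericVector offset, bool random_effect,
                   NumericVector alpha_init, NumericVector beta_init,
                   double sigma_init, NumericVector eps_init,
                   bool fix_alpha, int iterations, int burnin, int thin,
                   double prior_sd_coef, double prior_sd_sigma) {
  LikState st;
  st.I = counts.nrow(); st.J = counts.ncol();
  st.pab = X.ncol(); st.qdet = W.ncol();
  st.counts = INTEGER(counts);
  st.X = REAL(X); st.W = REAL(W); st.offset = REAL(offset);
  st.loglam.resize(st.I); st.pmat.resize(st.I * st.J); st.sll.resize(st.I);

  std::vector<double> alpha(alpha_init.begin(), alpha_init.end());
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> eps(eps_init.begin(), eps_init.end());
  double sigma = sigma_init;

  int d = (fix_alpha ? 0 : st.qdet) + st.pab; // coefficient block dimension
  std::vector<double> coef(d);
  auto pack = [&]() {
    int k = 0;
    if (!fix_alpha) for (int a = 0; a < st.qdet; ++a) coef[k++] = alpha[a];
    for (int b = 0; b < st.pab; ++b) coef[k++] = beta[b];
  };
  auto unpack = [&](const std::vector<double>& v, std::vector<double>& a,
                    std::vector<double>& b) {
    int k = 0;
    if (!fix_alpha) for (int q = 0; q < st.qdet; ++q) a[q] = v[k++];
    for (int p2 = 0; p2 < st.pab; ++p2) b[p2] = v[k++];
  };
  pack();

  update_p(st, alpha);
  update_loglam(st, beta, eps);
  double cur_ll = full_ll(st);

  auto coef_lp = [&](const std::vector<double>& v) {
    double lp = 0.0;
    for (int k = 0; k < d; ++k) lp += dnorm0(v[k], prior_sd_coef);
    return lp;
  };
  double cur_coef_lp = coef_lp(coef);

  // Haario adaptation state for the coefficient block
  std::vector<double> mu(coef), Cov(d * d, 0.0), chol(d * d, 0.0);
  double coef_scale = 0.1, eps_scale = 0.5, sig_scale = 0.5;
  int n_adapt = 1;
  bool have_chol = false;
  auto refresh_chol = [&]() {
    // chol of 2.38^2/d * Cov + jitter; fall back to diagonal on failure
    std::vector<double> A(Cov);
    double f = 5.6644 / d;
    for (int k = 0; k < d * d; ++k) A[k] *= f;
    for (int k = 0; k < d; ++k) A[k * d + k] += 1e-8;
    std::vector<double> L(d * d, 0.0);
    bool ok = true;
    for (int i2 = 0; i2 < d && ok; ++i2) {
      for (int j2 = 0; j2 <= i2; ++j2) {
        double s2 = A[i2 * d + j2];
        for (int k = 0; k < j2; ++k) s2 -= L[i2 * d + k] * L[j2 * d + k];
        if (i2 == j2) {
          if (s2 <= 0) { ok = false; break; }
          L[i2 * d + i2] = std::sqrt(s2);
        } else {
          L[i2 * d + j2] = s2 / L[j2 * d + j2];
        }
      }
    }
    if (ok) { chol = L; have_chol = true; }
  };

  int n_keep = (iterations > burnin) ? (iterations - burnin + thin - 1) / thin : 0;
  int n_par = st.qdet + st.pab + 1 + st.I;
  NumericMatrix draws(std::max(n_keep, 1), n_par);
  NumericMatrix ll_mat(std::max(n_keep, 1), st.I);
  int kept = 0;
  int acc_coef = 0, try_coef = 0, acc_eps = 0, try_eps = 0,
      acc_sig = 0, try_sig = 0;
  int batch_acc_coef = 0, batch_try_coef = 0, batch_acc_eps = 0,
      batch_try_eps = 0, batch_acc_sig = 0, batch_try_sig = 0;

  RNGScope scope;
  std::vector<double> prop(d), a_prop(st.qdet), b_prop(st.pab), z(d);

  for (int t = 1; t <= iterations; ++t) {
    bool adapting = t <= burnin;

    // --- coefficient block ---
    for (int k = 0; k < d; ++k) z[k] = norm_rand();
    if (have_chol) {
      for (int i2 = 0; i2 < d; ++i2) {
        double v = 0.0;
        for (int k = 0; k <= i2; ++k) v += chol[i2 * d + k] * z[k];
        prop[i2] = coef[i2] + coef_scale * v;
      }
    } else {
      for (int k = 0; k < d; ++k) prop[k] = coef[k] + coef_scale * z[k];
    }
    a_prop = alpha; b_prop = beta;
    unpack(prop, a_prop, b_prop);
    {
      std::vector<double> old_p(st.pmat), old_lam(st.loglam), old_sll(st.sll);
      if (!fix_alpha) update_p(st, a_prop);
      update_loglam(st, b_prop, eps);
      double new_ll = full_ll(st);
      double new_lp = coef_lp(prop);
      ++try_coef; ++batch_try_coef;
      if (std::log(unif_rand()) < new_ll + new_lp - cur_ll - cur_coef_lp) {
        coef = prop; alpha = a_prop; beta = b_prop;
        cur_ll = new_ll; cur_coef_lp = new_lp;
        ++acc_coef; ++batch_acc_coef;
      } else {
        st.pmat = old_p; st.loglam = old_lam; st.sll = old_sll;
      }
    }

    // --- site random effects ---
    if (random_effect) {
      for (int i2 = 0; i2 < st.I; ++i2) {
        double e_new = eps[i2] + eps_scale * norm_rand();
        double old_lam_i = st.loglam[i2];
        st.loglam[i2] = old_lam_i - eps[i2] + e_new;
        double ll_new = site_ll_cached(st, i2);
        double delta = ll_new - st.sll[i2]
          + dnorm0(e_new, sigma) - dnorm0(eps[i2], sigma);
        ++try_eps; ++batch_try_eps;
        if (std::log(unif_rand()) < delta) {
          cur_ll += ll_new - st.sll[i2];
          eps[i2] = e_new; st.sll[i2] = ll_new;
          ++acc_eps; ++batch_acc_eps;
        } else {
          st.loglam[i2] = old_lam_i;
        }
      }

      // --- sigma_eps (random walk on log scale; half-normal prior) ---
      double ls_new = std::log(sigma) + sig_scale * norm_rand();
      double s_new = std::exp(ls_new);
      double delta = 0.0;
      for (int i2 = 0; i2 < st.I; ++i2)
        delta += dnorm0(eps[i2], s_new) - dnorm0(eps[i2], sigma);
      delta += -0.5 * (s_new * s_new - sigma * sigma)
               / (prior_sd_sigma * prior_sd_sigma);
      delta += ls_new - std::log(sigma); // Jacobian of the log transform
      ++try_sig; ++batch_try_sig;
      if (std::log(unif_rand()) < delta) { sigma = s_new; ++acc_sig; ++batch_acc_sig; }
    }

    // --- adaptation (burn-in only; frozen afterward) ---
    if (adapting) {
      // running mean / covariance of the coefficient block
      double w = 1.0 / (n_adapt + 1);
      std::vector<double> dev(d);
      for (int k = 0; k < d; ++k) dev[k] = coef[k] - mu[k];
      for (int k = 0; k < d; ++k) mu[k] += w * dev[k];
      for (int i2 = 0; i2 < d; ++i2)
        for (int j2 = 0; j2 < d; ++j2)
          Cov[i2 * d + j2] += w * (dev[i2] * dev[j2] * (1.0 - w)
                                   - Cov[i2 * d + j2]);
      ++n_adapt;
      if (t % 50 == 0) {
        if (batch_try_coef > 0) {
          double r = (double)batch_acc_coef / batch_try_coef;
          coef_scale *= std::exp(r - 0.3);
        }
        if (batch_try_eps > 0) {
          double r = (double)batch_acc_eps / batch_try_eps;
          eps_scale *= std::exp(r - 0.35);
        }
        if (batch_try_sig > 0) {
          double r = (double)batch_acc_sig / batch_try_sig;
          sig_scale *= std::exp(r - 0.35);
        }
        batch_acc_coef = batch_try_coef = batch_acc_eps = batch_try_eps = 0;
        batch_acc_sig = batch_try_sig = 0;
        if (t >= 200) { refresh_chol(); coef_scale = std::min(coef_scale, 4.0); }
      }
    }

    // --- retain ---
    if (t > burnin && (t - burnin - 1) % thin == 0 && kept < n_keep) {
      int col = 0;
      for (int k = 0; k < st.qdet; ++k) draws(kept, col++) = alpha[k];
      for (int k = 0; k < st.pab; ++k) draws(kept, col++) = beta[k];
      draws(kept, col++) = sigma;
      for (int i2 = 0; i2 < st.I; ++i2) draws(kept, col++) = eps[i2];
      for (int i2 = 0; i2 < st.I; ++i2) ll_mat(kept, i2) = st.sll[i2];
      ++kept;
    }
  }

  return List::create(
    _["draws"] = draws, _["loglik"] = ll_mat, _["kept"] = kept,
    _["accept"] = NumericVector::create(
      _["coef"] = try_coef ? (double)acc_coef / try_coef : NA_REAL,
      _["eps"] = try_eps ? (double)acc_eps / try_eps : NA_REAL,
      _["sigma"] = try_sig ? (double)acc_sig / try_sig : NA_REAL),
    _["final_ll"] = cur_ll);
}
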