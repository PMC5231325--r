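#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for an overfitted univariate Gaussian mixture.
// Mirrors the exported R reference updates (allocation_full_conditional,
// sample_proportions, sample_means, sample_variances,
// update_hyperparameters) step for step; kept in C++ because the
// benchmark runs take ~10^4-10^5 sweeps over n*K allocation updates.

// log of a Gamma(shape, rate = 1) draw, stable for tiny shapes
static double rloggamma1(double shape) {
  if (shape >= 0.02) return std::log(R::rgamma(shape, 1.0));
  return std::log(R::rgamma(shape + 1.0, 1.0)) +
         std::log(R::unif_rand()) / shape;
}

// sigma^2 draw from kernel (s2)^(-n/2) exp(-ss/(2 s2)) truncated to
// (0, upper): rejection from the untruncated inverse-gamma when proper,
// grid inverse-CDF otherwise.
static double rtrunc_invgamma_var(int n, double ss, double upper) {
  if (n == 0) return R::unif_rand() * upper;
  double a = n / 2.0 - 1.0;
  if (a > 0) {
    for (int i = 0; i < 50; ++i) {
      double x = ss / 2.0 / R::rgamma(a, 1.0);
      if (x < upper) return x;
    }
  }
  const int G = 512;
  std::vector<double> w(G);
  double maxlog = R_NegInf;
  for (int g = 0; g < G; ++g) {
    double s2 = upper * (g + 0.5) / G;
    w[g] = -(n / 2.0) * std::log(s2) - ss / (2.0 * s2);
    if (w[g] > maxlog) maxlog = w[g];
  }
  double tot = 0.0;
  for (int g = 0; g < G; ++g) { w[g] = std::exp(w[g] - maxlog); tot += w[g]; }
  double u = R::unif_rand() * tot, c = 0.0;
  for (int g = 0; g < G; ++g) { c += w[g]; if (u <= c) return upper * (g + 0.5) / G; }
  return upper * (G - 0.5) / G;
}

// [[Rcpp::export]]
List gibbs_univariate_cpp(NumericVector y, int K, double alpha,
                          int mean_prior_type,  // 0 vague, 1 normal-gamma
                          double mean0, double var0,
                          int var_prior_type,   // 0 uniform, 1 hierarchical
                          double var_upper,
                          double nu1, double nu2, double M0_inv,
                          double beta1, double eps1,
                          double m0_data, double R_data,
                          int n_iter, int burn_in,
                          bool store_z, bool store_logf, int init_mode) {
  const int n = y.size();
  const double eps2 = (R_data > 0) ? 20.0 / (R_data * R_data) : 1.0;
  const double R2 = R_data * R_data;

  // state
  std::vector<double> llam(K, -std::log((double)K));
  std::vector<double> mu(K), sig2(K);
  std::vector<int> z(n);
  {
    NumericVector ys = clone(y).sort();
    double vy = 0.0, my = 0.0;
    for (int i = 0; i < n; ++i) my += y[i];
    my /= n;
    for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
    vy = (n > 1) ? vy / (n - 1) : 1.0;
    if (vy <= 0) vy = 1e-6;
    for (int k = 0; k < K; ++k) {
      if (init_mode == 0) {
        int idx = (int)std::floor((k + 0.5) / K * (n - 1) + 0.5);
        mu[k] = ys[idx];
      } else {
        mu[k] = ys[n / 2];  // all components start at the median
      }
      sig2[k] = vy;
    }
  }
  double b0 = m0_data, eta = nu1 / nu2, C0 = eps1 / eps2;

  // output
  NumericMatrix out_lambda(n_iter, K), out_mu(n_iter, K), out_sig2(n_iter, K);
  IntegerMatrix out_counts(n_iter, K);
  NumericVector out_ll_obs(n_iter), out_ll_comp(n_iter);
  NumericMatrix out_hyper(mean_prior_type == 1 || var_prior_type == 1 ?
                          n_iter : 0, 3);
  IntegerMatrix out_z(store_z ? n_iter : 0, n);
  NumericMatrix out_logf(store_logf ? n_iter : 0, n);

  std::vector<double> logp(K), cnst(K), sum_y(K);
  std::vector<int> counts(K);

  int total = burn_in + n_iter;
  for (int m = 0; m < total; ++m) {
    int rec = m - burn_in;
    // record the state entering this sweep; the allocations, occupancy
    // counts and log likelihoods drawn below condition on exactly this
    // state, so every stored row is internally consistent
    if (rec >= 0) {
      for (int k = 0; k < K; ++k) {
        out_lambda(rec, k) = std::exp(llam[k]);
        out_mu(rec, k) = mu[k];
        out_sig2(rec, k) = sig2[k];
      }
      if (out_hyper.nrow() > 0) {
        out_hyper(rec, 0) = b0;
        out_hyper(rec, 1) = eta;
        out_hyper(rec, 2) = C0;
      }
    }
    // per-class constants for the allocation sweep
    for (int k = 0; k < K; ++k) {
      cnst[k] = llam[k] - 0.5 * std::log(2.0 * M_PI * sig2[k]);
      counts[k] = 0;
      sum_y[k] = 0.0;
    }
    double ll_obs = 0.0, ll_comp = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double d = y[i] - mu[k];
        logp[k] = cnst[k] - d * d / (2.0 * sig2[k]);
        if (logp[k] > mx) mx = logp[k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { logp[k] = std::exp(logp[k] - mx); tot += logp[k]; }
      double logmix = mx + std::log(tot);
      ll_obs += logmix;
      double u = R::unif_rand() * tot, c = 0.0;
      int pick = K - 1;
      for (int k = 0; k < K; ++k) { c += logp[k]; if (u <= c) { pick = k; break; } }
      z[i] = pick;
      counts[pick]++;
      sum_y[pick] += y[i];
      double d = y[i] - mu[pick];
      ll_comp += cnst[pick] - d * d / (2.0 * sig2[pick]);
      if (store_logf && rec >= 0) out_logf(rec, i) = logmix;
      if (store_z && rec >= 0) out_z(rec, i) = pick + 1;
    }

    // proportions: Dirichlet(alpha + N) in log space
    {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        llam[k] = rloggamma1(alpha + counts[k]);
        if (llam[k] > mx) mx = llam[k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) tot += std::exp(llam[k] - mx);
      double lse = mx + std::log(tot);
      for (int k = 0; k < K; ++k) llam[k] -= lse;
    }

    // means: conjugate normal per class (empty classes draw from prior)
    double pm = (mean_prior_type == 0) ? mean0 : b0;
    double pv = (mean_prior_type == 0) ? var0 : eta * R2;
    if (pv <= 0) pv = 1e-12;
    for (int k = 0; k < K; ++k) {
      double prec = counts[k] / sig2[k] + 1.0 / pv;
      double mpost = (sum_y[k] / sig2[k] + pm / pv) / prec;
      mu[k] = R::rnorm(mpost, std::sqrt(1.0 / prec));
    }

    // variances: per-class sums of squares around the fresh means
    std::vector<double> ss(K, 0.0);
    for (int i = 0; i < n; ++i) {
      double d = y[i] - mu[z[i]];
      ss[z[i]] += d * d;
    }
    for (int k = 0; k < K; ++k) {
      if (var_prior_type == 1) {
        sig2[k] = 1.0 / R::rgamma(beta1 + counts[k] / 2.0,
                                  1.0 / (C0 + ss[k] / 2.0));
      } else {
        sig2[k] = rtrunc_invgamma_var(counts[k], ss[k], var_upper);
      }
    }

    // hyperparameters of the hierarchical priors
    if (mean_prior_type == 1) {
      double v_mu = eta * R2;
      double prec = M0_inv + K / v_mu;
      double sum_mu = 0.0;
      for (int k = 0; k < K; ++k) sum_mu += mu[k];
      double mpost = (m0_data * M0_inv + sum_mu / v_mu) / prec;
      b0 = R::rnorm(mpost, std::sqrt(1.0 / prec));
      double dev = 0.0;
      for (int k = 0; k < K; ++k) dev += (mu[k] - b0) * (mu[k] - b0);
      eta = R::rgamma(nu1 + K / 2.0, 1.0 / (nu2 + dev / (2.0 * R2)));
    }
    if (var_prior_type == 1) {
      double sum_prec = 0.0;
      for (int k = 0; k < K; ++k) sum_prec += 1.0 / sig2[k];
      C0 = R::rgamma(eps1 + K * beta1, 1.0 / (eps2 + sum_prec));
    }

    if (rec >= 0) {
      for (int k = 0; k < K; ++k) out_counts(rec, k) = counts[k];
      out_ll_obs[rec] = ll_obs;
      out_ll_comp[rec] = ll_comp;
    }
  }

  List out = List::create(
    _["lambda"] = out_lambda, _["means"] = out_mu,
    _["variances"] = out_sig2, _["counts"] = out_counts,
    _["loglik_obs"] = out_ll_obs, _["loglik_complete"] = out_ll_comp);
  if (out_hyper.nrow() > 0) out["hyper"] = out_hyper;
  if (store_z) out["z"] = out_z;
  if (store_logf) out["log_obs_density"] = out_logf;
  return out;
}
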