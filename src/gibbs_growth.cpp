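#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Blocked Gibbs sampler for an overfitted latent-class linear mixed model
// (growth mixture model): class-specific fixed effects theta_j, optional
// common fixed effects gamma, class-specific random-effect covariance
// Sigma_j, common residual variance. Subject allocation integrates the
// random effects out analytically (Woodbury identities on the r x r
// blocks); a conditional-on-b allocation variant is kept as an algebra
// cross-check.

static double rloggamma1(double shape) {
  if (shape >= 0.02) return std::log(R::rgamma(shape, 1.0));
  return std::log(R::rgamma(shape + 1.0, 1.0)) +
         std::log(R::unif_rand()) / shape;
}

// Draw from Wishart(df, S) via Bartlett; returns a p x p matrix.
static arma::mat rwishart(double df, const arma::mat& S) {
  const int p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

static arma::vec rmvnorm_prec(const arma::vec& lin, const arma::mat& prec) {
  // draw from N(prec^-1 lin, prec^-1)
  arma::mat U = arma::chol(prec);        // prec = U' U
  arma::vec mean_ = arma::solve(arma::trimatl(U.t()), lin);
  mean_ = arma::solve(arma::trimatu(U), mean_);
  arma::vec zr(lin.n_elem);
  for (arma::uword i = 0; i < zr.n_elem; ++i) zr(i) = R::norm_rand();
  return mean_ + arma::solve(arma::trimatu(U), zr);
}

// [[Rcpp::export]]
List gibbs_growth_cpp(arma::vec y, arma::ivec subj_start,
                      arma::mat X, arma::mat W, arma::mat Z,
                      int K, double alpha, double fe_var,
                      double resid_shape, double resid_rate,
                      double re_scale, double re_df,
                      int n_iter, int burn_in,
                      bool store_z, bool marginal_alloc, int init_mode,
                      bool share_re_cov) {
  const int ns = subj_start.n_elem - 1;
  const int p = X.n_cols, q = W.n_cols, r = Z.n_cols;
  const int n_rows = y.n_elem;
  const int ncov = r * (r + 1) / 2;

  // per-subject cross-product blocks
  std::vector<arma::mat> XtX(ns), XtZ(ns), XtW(ns), ZtZ(ns), ZtW(ns);
  std::vector<arma::vec> Xty(ns), Zty(ns), Wty(ns);
  std::vector<arma::mat> WtW(ns);
  std::vector<double> yty(ns);
  std::vector<int> Tlen(ns);
  for (int i = 0; i < ns; ++i) {
    int a = subj_start(i), b = subj_start(i + 1) - 1;
    Tlen[i] = b - a + 1;
    arma::mat Xi = X.rows(a, b), Zi = Z.rows(a, b);
    arma::vec yi = y.subvec(a, b);
    XtX[i] = Xi.t() * Xi;
    XtZ[i] = Xi.t() * Zi;
    ZtZ[i] = Zi.t() * Zi;
    Xty[i] = Xi.t() * yi;
    Zty[i] = Zi.t() * yi;
    yty[i] = arma::dot(yi, yi);
    if (q > 0) {
      arma::mat Wi = W.rows(a, b);
      XtW[i] = Xi.t() * Wi;
      ZtW[i] = Zi.t() * Wi;
      WtW[i] = Wi.t() * Wi;
      Wty[i] = Wi.t() * yi;
    }
  }

  // initialization: intercepts at quantiles of per-subject mean response,
  // remaining fixed effects at 0, small random-effect covariance
  arma::vec subj_mean(ns);
  for (int i = 0; i < ns; ++i) {
    int a = subj_start(i), b = subj_start(i + 1) - 1;
    subj_mean(i) = arma::mean(y.subvec(a, b));
  }
  arma::vec sm = arma::sort(subj_mean);
  arma::mat theta(p, K, arma::fill::zeros);
  if (init_mode == 0) {
    // spread: class intercepts at quantiles of the subject means
    for (int k = 0; k < K; ++k) {
      int idx = (int)std::floor((k + 0.5) / K * (ns - 1) + 0.5);
      theta(0, k) = sm(idx);
    }
  } else {
    // common: every class starts at the pooled mean; classes
    // differentiate during burn-in and superfluous ones empty
    for (int k = 0; k < K; ++k) theta(0, k) = arma::mean(subj_mean);
  }
  arma::vec gam(std::max(q, 1), arma::fill::zeros);
  // start tight: classes sit at quantiles of the subject means with small
  // within-class spread, so the sparse prior prunes from many occupied
  // classes instead of splitting from few
  double v_sm = arma::var(subj_mean);
  std::vector<arma::mat> Sigma(K), Sigma_inv(K);
  for (int k = 0; k < K; ++k) {
    Sigma[k] = arma::eye(r, r) * std::max(v_sm / 50.0, 1e-6);
    if (r >= 2) for (int d = 1; d < r; ++d) Sigma[k](d, d) /= 100.0;
    Sigma_inv[k] = arma::inv_sympd(Sigma[k]);
  }
  double sig2 = std::max(arma::var(y) / 10.0, 1e-8);
  std::vector<double> llam(K, -std::log((double)K));
  arma::mat b_re(r, ns, arma::fill::zeros);
  std::vector<int> z(ns, 0);
  arma::mat S0 = arma::eye(r, r) * re_scale;

  // output
  NumericMatrix out_lambda(n_iter, K), out_theta(n_iter, K * p),
      out_gamma(n_iter, std::max(q, 0)), out_Sigma(n_iter, K * ncov);
  NumericVector out_sig2(n_iter), out_ll_obs(n_iter);
  IntegerMatrix out_counts(n_iter, K);
  IntegerMatrix out_z(store_z ? n_iter : 0, ns);

  std::vector<double> logp(K);
  std::vector<int> counts(K);

  int total = burn_in + n_iter;
  for (int m = 0; m < total; ++m) {
    int rec = m - burn_in;
    // record the state entering this sweep; allocations and the marginal
    // log likelihood below condition on exactly this state
    if (rec >= 0) {
      for (int k = 0; k < K; ++k) {
        out_lambda(rec, k) = std::exp(llam[k]);
        for (int d = 0; d < p; ++d) out_theta(rec, k * p + d) = theta(d, k);
        int c = 0;
        for (int d1 = 0; d1 < r; ++d1)
          for (int d2 = d1; d2 < r; ++d2)
            out_Sigma(rec, k * ncov + c++) = Sigma[k](d1, d2);
      }
      for (int d = 0; d < q; ++d) out_gamma(rec, d) = gam(d);
      out_sig2[rec] = sig2;
    }

    // ---- subject allocation ----
    std::vector<double> logdet_Sigma(K);
    for (int k = 0; k < K; ++k) {
      counts[k] = 0;
      logdet_Sigma[k] = arma::log_det_sympd(Sigma[k]);
    }
    double ll_obs = 0.0;
    for (int i = 0; i < ns; ++i) {
      // ete0/Zte0: parts not involving theta
      double ete0 = yty[i];
      arma::vec Zte0 = Zty[i];
      if (q > 0) {
        ete0 += -2.0 * arma::dot(Wty[i], gam) +
                arma::as_scalar(gam.t() * WtW[i] * gam);
        Zte0 -= ZtW[i] * gam;
      }
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        arma::vec th = theta.col(k);
        arma::vec Xty_adj = Xty[i];
        if (q > 0) Xty_adj -= XtW[i] * gam;
        double ete = ete0 - 2.0 * arma::dot(Xty_adj, th) +
                     arma::as_scalar(th.t() * XtX[i] * th);
        arma::vec Zte = Zte0 - XtZ[i].t() * th;
        double logdens;
        if (marginal_alloc) {
          arma::mat A = sig2 * Sigma_inv[k] + ZtZ[i];
          arma::mat Ai = arma::inv_sympd(A);
          // e' V^-1 e = e'e/sig2 - Zte' (sig2 Sigma^-1 + Z'Z)^-1 Zte / sig2
          double quad = (ete - arma::as_scalar(Zte.t() * Ai * Zte)) / sig2;
          // det(sig2 I + Z Sigma Z') = sig2^(T-r) det(Sigma) det(A)
          double logdetV = (Tlen[i] - r) * std::log(sig2) +
              logdet_Sigma[k] + arma::log_det_sympd(A);
          logdens = -0.5 * (Tlen[i] * std::log(2.0 * M_PI) + logdetV + quad);
        } else {
          // condition on the current random effects draw
          arma::vec bi = b_re.col(i);
          double ess = ete - 2.0 * arma::dot(Zte, bi) +
              arma::as_scalar(bi.t() * ZtZ[i] * bi);
          logdens = -0.5 * (Tlen[i] * std::log(2.0 * M_PI * sig2) +
                            ess / sig2) -
              0.5 * (r * std::log(2.0 * M_PI) + logdet_Sigma[k] +
                     arma::as_scalar(bi.t() * Sigma_inv[k] * bi));
        }
        logp[k] = llam[k] + logdens;
        if (logp[k] > mx) mx = logp[k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { logp[k] = std::exp(logp[k] - mx); tot += logp[k]; }
      ll_obs += mx + std::log(tot);
      double u = R::unif_rand() * tot, c = 0.0;
      int pick = K - 1;
      for (int k = 0; k < K; ++k) { c += logp[k]; if (u <= c) { pick = k; break; } }
      z[i] = pick;
      counts[pick]++;
    }

    // ---- random effects ----
    for (int i = 0; i < ns; ++i) {
      int k = z[i];
      arma::vec th = theta.col(k);
      arma::vec Zte = Zty[i] - XtZ[i].t() * th;
      if (q > 0) Zte -= ZtW[i] * gam;
      arma::mat prec = ZtZ[i] / sig2 + Sigma_inv[k];
      b_re.col(i) = rmvnorm_prec(Zte / sig2, prec);
    }

    // ---- class-specific fixed effects ----
    for (int k = 0; k < K; ++k) {
      arma::mat prec = arma::eye(p, p) / fe_var;
      arma::vec lin(p, arma::fill::zeros);
      for (int i = 0; i < ns; ++i) {
        if (z[i] != k) continue;
        prec += XtX[i] / sig2;
        arma::vec xt = Xty[i] - XtZ[i] * b_re.col(i);
        if (q > 0) xt -= XtW[i] * gam;
        lin += xt / sig2;
      }
      theta.col(k) = rmvnorm_prec(lin, prec);
    }

    // ---- common fixed effects ----
    if (q > 0) {
      arma::mat prec = arma::eye(q, q) / fe_var;
      arma::vec lin(q, arma::fill::zeros);
      for (int i = 0; i < ns; ++i) {
        prec += WtW[i] / sig2;
        arma::vec wt = Wty[i] - XtW[i].t() * theta.col(z[i]) -
                       ZtW[i].t() * b_re.col(i);
        lin += wt / sig2;
      }
      gam = rmvnorm_prec(lin, prec);
    }

    // ---- random-effect covariances ----
    if (share_re_cov) {
      // one covariance pooled over all classes
      if (r == 1) {
        double ssb = 0.0;
        for (int i = 0; i < ns; ++i) ssb += b_re(0, i) * b_re(0, i);
        double tau = R::rgamma(resid_shape + ns / 2.0,
                               1.0 / (resid_rate + ssb / 2.0));
        for (int k = 0; k < K; ++k) {
          Sigma[k](0, 0) = 1.0 / tau;
          Sigma_inv[k](0, 0) = tau;
        }
      } else {
        arma::mat Spost = S0;
        for (int i = 0; i < ns; ++i)
          Spost += b_re.col(i) * b_re.col(i).t();
        arma::mat Wdraw = rwishart(re_df + ns, arma::inv_sympd(Spost));
        for (int k = 0; k < K; ++k) {
          Sigma_inv[k] = Wdraw;
          Sigma[k] = arma::inv_sympd(Wdraw);
        }
      }
    } else for (int k = 0; k < K; ++k) {
      if (r == 1) {
        double ssb = 0.0;
        for (int i = 0; i < ns; ++i)
          if (z[i] == k) ssb += b_re(0, i) * b_re(0, i);
        double tau = R::rgamma(resid_shape + counts[k] / 2.0,
                               1.0 / (resid_rate + ssb / 2.0));
        Sigma[k](0, 0) = 1.0 / tau;
        Sigma_inv[k](0, 0) = tau;
      } else {
        arma::mat Spost = S0;
        for (int i = 0; i < ns; ++i)
          if (z[i] == k) Spost += b_re.col(i) * b_re.col(i).t();
        arma::mat Wdraw = rwishart(re_df + counts[k],
                                   arma::inv_sympd(Spost));
        Sigma_inv[k] = Wdraw;
        Sigma[k] = arma::inv_sympd(Wdraw);
      }
    }

    // ---- residual variance ----
    {
      double rss = 0.0;
      for (int i = 0; i < ns; ++i) {
        int k = z[i];
        arma::vec th = theta.col(k), bi = b_re.col(i);
        arma::vec Xty_adj = Xty[i];
        double ete = yty[i];
        if (q > 0) {
          ete += -2.0 * arma::dot(Wty[i], gam) +
                 arma::as_scalar(gam.t() * WtW[i] * gam);
          Xty_adj -= XtW[i] * gam;
        }
        ete += -2.0 * arma::dot(Xty_adj, th) +
               arma::as_scalar(th.t() * XtX[i] * th);
        arma::vec Zte = Zty[i] - XtZ[i].t() * th;
        if (q > 0) Zte -= ZtW[i] * gam;
        rss += ete - 2.0 * arma::dot(Zte, bi) +
               arma::as_scalar(bi.t() * ZtZ[i] * bi);
      }
      double tau = R::rgamma(resid_shape + n_rows / 2.0,
                             1.0 / (resid_rate + rss / 2.0));
      sig2 = 1.0 / tau;
    }

    // ---- mixing proportions ----
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

    if (rec >= 0) {
      for (int k = 0; k < K; ++k) out_counts(rec, k) = counts[k];
      out_ll_obs[rec] = ll_obs;
      if (store_z) for (int i = 0; i < ns; ++i) out_z(rec, i) = z[i] + 1;
    }
  }

  List out = List::create(
    _["lambda"] = out_lambda, _["theta"] = out_theta,
    _["gamma"] = out_gamma, _["Sigma"] = out_Sigma,
    _["resid_var"] = out_sig2, _["counts"] = out_counts,
    _["loglik_obs"] = out_ll_obs);
  if (store_z) out["z"] = out_z;
  return out;
}
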