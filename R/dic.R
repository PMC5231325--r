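#' Mixture-adapted deviance information criterion DIC3
#'
#' `DIC3 = -4 E[log f(y | theta) | y] + 2 log fhat(y)` where the
#' predictive density `fhat(y_i)` is the posterior mean, across retained
#' iterations, of the mixture density of observation i. The first term is
#' estimated by the average observed-data log likelihood over the chain;
#' the per-observation averaging of the second term is done by
#' log-mean-exp over iterations so that small densities cannot underflow.
#'
#' @param draws A `"mixture_draws"` object fitted with
#'   `store_obs_density = TRUE`, or a numeric vector of per-iteration
#'   observed-data log likelihoods (in which case `log_obs_density` must
#'   be supplied).
#' @param log_obs_density Optional iterations x observations matrix of
#'   log mixture densities, used when `draws` is a plain vector.
#' @return The DIC3 value (smaller is better).
#' @export
dic3 <- function(draws, log_obs_density = NULL) {
  if (inherits(draws, "mixture_draws")) {
    if (is.null(draws$log_obs_density))
      stop("fit with store_obs_density = TRUE to compute DIC3")
    ll <- draws$loglik_obs
    lf <- draws$log_obs_density
  } else {
    ll <- as.numeric(draws)
    lf <- log_obs_density
    if (is.null(lf)) stop("log_obs_density matrix required")
  }
  if (length(ll) < 1L) stop("no retained iterations")
  log_fhat <- apply(lf, 2L, function(x) logsumexp(x) - log(length(x)))
  if (any(!is.finite(log_fhat)))
    stop("zero predictive density for some observation")
  -4 * mean(ll) + 2 * sum(log_fhat)
}

#' Mixture-adapted deviance information criterion DIC4
#'
#' `DIC4 = -4 E[log f(y, Z | theta) | y] +
#'  2 E_Z[log f(y, Z | E[theta | y, Z]) | y]`, the complete-data analogue
#' of DIC3. The first term is the average complete-data log likelihood
#' over the chain. For the second term, each retained allocation vector
#' `z^(m)` is plugged into the closed-form conditional posterior means of
#' the parameters given `Z = z^(m)` under the model's conjugate
#' structure -- Dirichlet mean for the proportions, the conjugate normal
#' mean for each class mean, and the conditional posterior mean of each
#' class variance (computed on the truncated support under the uniform
#' prior, or the inverse-gamma mean under the hierarchical prior) -- and
#' the complete-data log likelihood is evaluated there and averaged over
#' iterations. Components empty under `z^(m)` use their prior means.
#'
#' @param draws A `"mixture_draws"` object fitted with `store_z = TRUE`.
#' @return The DIC4 value (smaller is better).
#' @export
dic4 <- function(draws) {
  stopifnot(inherits(draws, "mixture_draws"))
  if (is.null(draws$z)) stop("fit with store_z = TRUE to compute DIC4")
  M <- nrow(draws$z)
  if (M < 1L) stop("no retained iterations")
  y <- draws$y
  n <- length(y)
  K <- draws$K_max
  prior <- draws$prior
  alpha <- prior$alpha
  term2 <- numeric(M)
  for (m in seq_len(M)) {
    z <- draws$z[m, ]
    N_j <- tabulate(z, nbins = K)
    sum_j <- vapply(seq_len(K), function(k) sum(y[z == k]), 0)
    mean_j <- ifelse(N_j > 0, sum_j / pmax(N_j, 1), 0)
    ss_j <- vapply(seq_len(K), function(k)
      if (N_j[k] > 0) sum((y[z == k] - mean_j[k])^2) else 0, 0)
    lam_hat <- (alpha + N_j) / (K * alpha + n)
    if (prior$var_prior == "hierarchical") {
      C0 <- if (!is.null(draws$hyper)) draws$hyper[m, 3] else prior$eps1
      s2_hat <- (C0 + ss_j / 2) / (prior$beta1 + N_j / 2 - 1)
    } else {
      s2_hat <- vapply(seq_len(K), function(k)
        trunc_invgamma_var_mean(N_j[k], ss_j[k], prior$var_upper), 0)
    }
    if (prior$mean_prior == "vague") {
      pm <- prior$mean0; pv <- prior$var0
    } else {
      pm <- draws$hyper[m, 1]
      pv <- draws$hyper[m, 2] * diff(range(y))^2
    }
    mu_hat <- (sum_j / s2_hat + pm / pv) / (N_j / s2_hat + 1 / pv)
    term2[m] <- sum(log(lam_hat[z]) +
                    dnorm(y, mu_hat[z], sqrt(s2_hat[z]), log = TRUE))
  }
  -4 * mean(draws$loglik_complete) + 2 * mean(term2)
}

## E[sigma^2] for the kernel (s2)^(-n/2) exp(-ss/(2 s2)) on (0, upper),
## by grid integration (proper for every n >= 0 thanks to the truncation).
trunc_invgamma_var_mean <- function(n, ss, upper) {
  if (n == 0L) return(upper / 2)
  grid <- upper * (seq_len(512) - 0.5) / 512
  logd <- -(n / 2) * log(grid) - ss / (2 * grid)
  w <- exp(logd - max(logd))
  sum(w * grid) / sum(w)
}

#' Select the number of classes by DIC
#'
#' Fits an ordinary (non-overfitted) mixture at each candidate K with the
#' same Gibbs machinery (`K_max = K`) and returns the K minimizing the
#' chosen deviance criterion, ties broken toward smaller K.
#'
#' @param data A `"univariate_dataset"` or numeric vector.
#' @param K_range Candidate numbers of classes.
#' @param prior A [univariate_prior()].
#' @param config An [mcmc_config()]; its `K_max` is overridden per
#'   candidate, and the needed storage flags are switched on
#'   automatically.
#' @param criterion `"dic3"` or `"dic4"`.
#' @return A `"criterion_result"` with `selected_K` and `values_by_K`.
#' @export
select_K_by_dic <- function(data, K_range, prior, config,
                            criterion = c("dic3", "dic4")) {
  criterion <- match.arg(criterion)
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) < 1L) stop("empty K range")
  vals <- vapply(K_range, function(K) {
    cfg <- mcmc_config(K_max = K, n_iter = config$n_iter,
                       burn_in = config$burn_in, seed = config$seed + K,
                       store_z = criterion == "dic4",
                       store_obs_density = criterion == "dic3")
    fit <- suppressWarnings(run_gibbs_univariate(data, prior, cfg))
    if (criterion == "dic3") dic3(fit) else dic4(fit)
  }, 0)
  names(vals) <- K_range
  structure(list(criterion = toupper(criterion),
                 selected_K = K_range[which.min(vals)],
                 values_by_K = vals),
            class = "criterion_result")
}
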