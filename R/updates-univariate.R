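## Reference (pure R) implementations of the Gibbs full conditionals for
## the overfitted univariate Gaussian mixture. The compiled sampler in
## src/ mirrors these step for step; keeping them exported makes every
## update individually testable against its conjugate closed form.

#' Allocation full conditional for one observation
#'
#' Posterior class membership probabilities for a single observation given
#' the current mixture parameters: `p_j` proportional to
#' `lambda_j * N(y | mu_j, sigma_j^2)`, computed in log space with
#' max-subtraction to avoid underflow.
#'
#' @param y A single observation.
#' @param lambda Mixing proportions (nonnegative, not all zero).
#' @param means,variances Class means and variances.
#' @return A probability vector over classes.
#' @examples
#' allocation_full_conditional(1, c(.5, .5), c(1, 3), c(1, 1))
#' @export
allocation_full_conditional <- function(y, lambda, means, variances) {
  stopifnot(length(lambda) == length(means),
            length(means) == length(variances), all(variances > 0))
  if (all(lambda == 0)) stop("all mixing proportions are zero")
  logp <- log(lambda) - 0.5 * log(2 * pi * variances) -
    (y - means)^2 / (2 * variances)
  logp <- logp - max(logp[is.finite(logp)])
  p <- exp(logp)
  p[!is.finite(p)] <- 0
  p / sum(p)
}

#' Sample mixing proportions from their full conditional
#'
#' Conjugate update of the symmetric Dirichlet(alpha) prior: a draw from
#' `Dirichlet(alpha + N_1, ..., alpha + N_K)` given the class occupancy
#' counts. Shapes below 0.02 are drawn through the
#' `Gamma(shape + 1) * U^(1/shape)` representation in log space, so the
#' update is stable down to the very small alphas used for sparse
#' overfitted mixtures.
#'
#' @param counts Nonnegative occupancy counts, one per class.
#' @param alpha Dirichlet hyperparameter (> 0).
#' @return A proportion vector summing to 1.
#' @export
sample_proportions <- function(counts, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  if (any(counts < 0)) stop("counts must be nonnegative")
  lg <- rloggamma(length(counts), alpha + counts)
  lg <- lg - logsumexp(lg)
  exp(lg)
}

## log of a Gamma(shape, rate = 1) draw, stable for tiny shapes
rloggamma <- function(n, shape) {
  out <- numeric(n)
  small <- shape < 0.02
  if (any(!small)) out[!small] <- log(rgamma(sum(!small), shape[!small]))
  if (any(small)) {
    s <- shape[small]
    out[small] <- log(rgamma(sum(small), s + 1)) + log(runif(sum(small))) / s
  }
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Sample class means from their full conditionals
#'
#' Conjugate normal update per class. Under the vague prior the prior is
#' `N(mean0, var0)`; under the normal-gamma prior it is
#' `N(b0, eta * R^2)` with `(b0, eta)` taken from `hyper_state`. Classes
#' with no allocated observations draw from the prior, which keeps the
#' chain on the full K-dimensional parameter space.
#'
#' @param y Data vector.
#' @param z Integer allocations in `1..K`.
#' @param variances Current class variances (length K).
#' @param prior A [univariate_prior()].
#' @param hyper_state List with `b0`, `eta`, `C0` (normal-gamma case) and
#'   `R` (data range); ignored for the vague prior.
#' @return A vector of K mean draws.
#' @export
sample_means <- function(y, z, variances, prior, hyper_state = NULL) {
  K <- length(variances)
  if (prior$mean_prior == "vague") {
    m0 <- prior$mean0; v0 <- prior$var0
  } else {
    m0 <- hyper_state$b0; v0 <- hyper_state$eta * hyper_state$R^2
  }
  if (v0 <= 0) stop("prior variance for the means must be positive")
  mu <- numeric(K)
  for (k in seq_len(K)) {
    idx <- z == k
    n_k <- sum(idx)
    prec <- n_k / variances[k] + 1 / v0
    mean_post <- (sum(y[idx]) / variances[k] + m0 / v0) / prec
    mu[k] <- rnorm(1, mean_post, sqrt(1 / prec))
  }
  mu
}

#' Sample class variances from their full conditionals
#'
#' Under the hierarchical prior the precision `1/sigma_k^2` has a conjugate
#' Gamma update with shape `beta1 + N_k/2` and rate `C0 + SS_k/2`
#' (shape-rate convention; `C0` is the rate of the Gamma prior on the
#' precisions, which keeps the `C0` hyperparameter itself conditionally
#' conjugate). Under the `U(0, var_upper)` prior the
#' conditional for `sigma_k^2` is an inverse-gamma kernel truncated to
#' `(0, var_upper)`; it is sampled by rejection from the untruncated
#' conditional, falling back to inverse-CDF sampling on a log-density grid
#' when the acceptance rate is very low or when fewer than 3 observations
#' make the untruncated kernel non-integrable. Empty classes revert to the
#' prior.
#'
#' @inheritParams sample_means
#' @param means Current class means (length K).
#' @return A vector of K variance draws.
#' @export
sample_variances <- function(y, z, means, prior, hyper_state = NULL) {
  K <- length(means)
  s2 <- numeric(K)
  for (k in seq_len(K)) {
    idx <- z == k
    n_k <- sum(idx)
    ss <- sum((y[idx] - means[k])^2)
    if (prior$var_prior == "hierarchical") {
      s2[k] <- 1 / rgamma(1, shape = prior$beta1 + n_k / 2,
                          rate = hyper_state$C0 + ss / 2)
    } else {
      s2[k] <- rtrunc_invgamma_var(n_k, ss, prior$var_upper)
    }
  }
  s2
}

## sigma^2 | ... proportional to (s2)^(-n/2) exp(-ss/(2 s2)) on (0, upper)
rtrunc_invgamma_var <- function(n, ss, upper) {
  if (upper <= 0) stop("empty truncation region")
  if (n == 0L) return(runif(1, 0, upper))
  a <- n / 2 - 1
  if (a > 0) {
    for (i in 1:50) {
      x <- ss / 2 / rgamma(1, shape = a)  # inverse-gamma(a, rate ss/2)
      if (x < upper) return(x)
    }
  }
  ## grid inverse-CDF fallback (also the n = 1, 2 case)
  grid <- upper * (seq_len(512) - 0.5) / 512
  logd <- -(n / 2) * log(grid) - ss / (2 * grid)
  w <- exp(logd - max(logd))
  grid[findInterval(runif(1) * sum(w), cumsum(w)) + 1L]
}

#' Update the normal-gamma hyperparameters
#'
#' Conjugate draws of the hierarchical prior state given the current class
#' means and variances: `b0 | means` combines its `N(m0, M0)` prior with
#' the K normal likelihoods of variance `eta * R^2`; `eta | means` has a
#' Gamma update with shape `nu1 + K/2` and rate
#' `nu2 + sum((mu_k - b0)^2) / (2 R^2)`; `C0 | precisions` has a Gamma
#' update with shape `eps1 + K * beta1` and rate
#' `eps2 + sum(1/sigma_k^2)`, where `eps2 = 20 / R^2`.
#'
#' @param means,variances Current class means and variances.
#' @param prior A [univariate_prior()] with hierarchical components active.
#' @param data_summary List with `m0` (data median) and `R` (data range).
#' @param hyper_state Current hyperparameter state (`b0`, `eta`, `C0`).
#' @return Updated `hyper_state` list with elements `b0`, `eta`, `C0`, `R`.
#' @export
update_hyperparameters <- function(means, variances, prior, data_summary,
                                   hyper_state) {
  R <- data_summary$R
  if (R == 0) stop("data range is zero; hierarchical prior undefined")
  K <- length(means)
  m0 <- data_summary$m0
  M0 <- 1 / prior$M0_inv
  ## b0 | means
  v_mu <- hyper_state$eta * R^2
  prec <- 1 / M0 + K / v_mu
  mean_post <- (m0 / M0 + sum(means) / v_mu) / prec
  b0 <- rnorm(1, mean_post, sqrt(1 / prec))
  ## eta | means, b0
  eta <- rgamma(1, shape = prior$nu1 + K / 2,
                rate = prior$nu2 + sum((means - b0)^2) / (2 * R^2))
  ## C0 | precisions
  eps2 <- 20 / R^2
  C0 <- rgamma(1, shape = prior$eps1 + K * prior$beta1,
               rate = eps2 + sum(1 / variances))
  list(b0 = b0, eta = eta, C0 = C0, R = R)
}
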