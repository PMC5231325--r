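#' Prior specification for the overfitted univariate Gaussian mixture
#'
#' The mixing proportions always get a symmetric Dirichlet(alpha) prior.
#' Two families are available for the class-specific means and variances:
#'
#' * **vague**: `mu_j ~ N(0, 1000)` and `sigma_j^2 ~ U(0, 10)`.
#' * **hierarchical** (normal-gamma): `mu_k | b0, eta ~ N(b0, eta * R^2)`
#'   with `b0 ~ N(m0, M0)` (`M0^{-1} = 1e-7`, i.e. essentially flat) and
#'   `eta ~ Gamma(nu1 = 0.5, nu2 = 0.5)`; and
#'   `1/sigma_k^2 ~ Gamma(beta1 = 1.25, beta2)` with the rate `beta2`
#'   controlled by a hyperparameter `C0 ~ Gamma(eps1 = 0.25, eps2 = 20/R^2)`.
#'   `m0` and `R` are the median and range of the data; they are filled in
#'   at fitting time. All Gamma distributions use the shape-rate
#'   convention.
#'
#' For a univariate location-scale mixture the number of class-specific
#' parameters is d = 2 (mean and variance), so the sparse-Dirichlet theory
#' requires `alpha < 1` for superfluous classes to empty asymptotically;
#' a warning (not an error) is raised for larger values, which remain
#' useful for studying the criterion's failure modes.
#'
#' @param alpha Symmetric Dirichlet hyperparameter (> 0).
#' @param mean_prior `"vague"` or `"normal_gamma"`.
#' @param var_prior `"uniform"` or `"hierarchical"`.
#' @param mean0,var0 Vague normal prior mean and variance for the class
#'   means.
#' @param var_upper Upper bound of the uniform prior on the class variances.
#' @param nu1,nu2 Shape and rate of the Gamma prior on `eta`.
#' @param M0_inv Prior precision of `b0`.
#' @param beta1 Shape of the Gamma prior on the class precisions.
#' @param eps1 Shape of the Gamma prior on `C0` (its rate is `20/R^2`).
#' @return An object of class `"univariate_prior"`.
#' @examples
#' univariate_prior(alpha = 0.01)
#' univariate_prior(alpha = 0.05, mean_prior = "normal_gamma",
#'                  var_prior = "hierarchical")
#' @export
univariate_prior <- function(alpha,
                             mean_prior = c("vague", "normal_gamma"),
                             var_prior = c("uniform", "hierarchical"),
                             mean0 = 0, var0 = 1000, var_upper = 10,
                             nu1 = 0.5, nu2 = 0.5, M0_inv = 1e-7,
                             beta1 = 1.25, eps1 = 0.25) {
  mean_prior <- match.arg(mean_prior)
  var_prior <- match.arg(var_prior)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single positive number")
  if (var0 <= 0 || var_upper <= 0 || nu1 <= 0 || nu2 <= 0 || M0_inv <= 0 ||
      beta1 <= 0 || eps1 <= 0)
    stop("all prior scale/shape parameters must be positive")
  d <- 2L  # class-specific mean and variance
  if (alpha >= d / 2)
    warning("alpha = ", alpha, " is not below d/2 = ", d / 2,
            "; superfluous classes are not guaranteed to empty", call. = FALSE)
  structure(list(alpha = alpha, mean_prior = mean_prior,
                 var_prior = var_prior, mean0 = mean0, var0 = var0,
                 var_upper = var_upper, nu1 = nu1, nu2 = nu2,
                 M0_inv = M0_inv, beta1 = beta1, eps1 = eps1, d = d),
            class = "univariate_prior")
}

#' Prior specification for the overfitted growth mixture model
#'
#' Class-specific and common fixed effects get independent
#' `N(0, fixed_effect_var)` priors; the residual precision gets a
#' `Gamma(resid_shape, resid_rate)` prior (equivalently an inverse-gamma on
#' the variance); the class-specific random-effect covariance gets an
#' inverse-Wishart prior with `re_df` degrees of freedom and scale matrix
#' `diag(re_scale)` (density proportional to
#' `|S|^{-(df+p+1)/2} exp(-tr(scale S^{-1})/2)`), reducing to a
#' `Gamma(resid_shape, resid_rate)` prior on the random-intercept precision
#' when there is a single random term. Mixing proportions get a symmetric
#' Dirichlet(alpha).
#'
#' @param alpha Symmetric Dirichlet hyperparameter (> 0).
#' @param fixed_effect_var Prior variance of each fixed effect.
#' @param resid_shape,resid_rate Gamma prior on the residual precision.
#' @param re_scale Diagonal value of the inverse-Wishart scale matrix.
#' @param re_df Inverse-Wishart degrees of freedom.
#' @return An object of class `"growth_prior"`.
#' @export
growth_prior <- function(alpha, fixed_effect_var = 1e3,
                         resid_shape = 1e-3, resid_rate = 1e-3,
                         re_scale = 1e-3, re_df = 3) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single positive number")
  if (fixed_effect_var <= 0 || resid_shape <= 0 || resid_rate <= 0 ||
      re_scale <= 0)
    stop("prior variances, shapes and rates must be positive")
  structure(list(alpha = alpha, fixed_effect_var = fixed_effect_var,
                 resid_shape = resid_shape, resid_rate = resid_rate,
                 re_scale = re_scale, re_df = re_df),
            class = "growth_prior")
}

#' MCMC configuration
#'
#' @param K_max Number of components of the overfitted model (default 10).
#'   For the deliberate-overfitting workflow `K_max` should exceed the
#'   number of classes believed plausible; values down to 1 are accepted so
#'   that the same machinery can fit ordinary (non-overfitted) mixtures,
#'   e.g. for DIC-based selection.
#' @param n_iter Number of retained iterations after burn-in
#'   (default 50000).
#' @param burn_in Number of discarded initial iterations (default 5000).
#' @param seed Integer seed making the whole chain reproducible.
#' @param store_z Store the per-iteration allocation vectors (needed for
#'   DIC4)?
#' @param store_obs_density Store the per-iteration, per-observation log
#'   mixture density (needed for DIC3)?
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(K_max = 10L, n_iter = 50000L, burn_in = 5000L,
                        seed = 1L, store_z = FALSE,
                        store_obs_density = FALSE) {
  K_max <- as.integer(K_max)
  n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in)
  if (K_max < 1L) stop("K_max must be at least 1")
  if (n_iter < 0L || burn_in < 0L) stop("n_iter and burn_in must be >= 0")
  structure(list(K_max = K_max, n_iter = n_iter, burn_in = burn_in,
                 seed = as.integer(seed), store_z = isTRUE(store_z),
                 store_obs_density = isTRUE(store_obs_density)),
            class = "mcmc_config")
}

#' Recommended Dirichlet hyperparameter
#'
#' The sparse-Dirichlet theory requires `alpha < d/2`, with d the number of
#' class-specific parameters, for superfluous components to empty; values
#' slightly below the threshold select the number of classes best in
#' simulations. The default recommendation is `0.85 * d/2`.
#'
#' @param d Number of class-specific parameters (2 for a univariate
#'   location-scale mixture; fixed effects plus free covariance entries for
#'   a growth mixture).
#' @param fraction Fraction of the `d/2` threshold to use.
#' @return A single numeric alpha.
#' @examples
#' recommended_alpha(2)  # univariate mixture
#' recommended_alpha(5)  # random intercept + slope growth mixture
#' @export
recommended_alpha <- function(d, fraction = 0.85) {
  stopifnot(d >= 1, fraction > 0, fraction < 1)
  fraction * d / 2
}
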