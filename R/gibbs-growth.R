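#' Gibbs sampler for the overfitted growth mixture model
#'
#' Blocked Gibbs sampling for a latent-class linear mixed-effects model
#' with `config$K_max` classes: subject-level allocations are drawn from
#' the marginal subject likelihood with the random effects integrated out
#' analytically, then subject random effects (conjugate multivariate
#' normal), class-specific fixed effects and common fixed effects
#' (conjugate normal), class-specific random-effect covariances
#' (conjugate inverse-Wishart, or a conjugate gamma precision update for
#' a single random intercept) and the common residual precision
#' (conjugate gamma). Occupancy is counted over subjects: the subject is
#' the exchangeable unit of a longitudinal mixture, so the empty-class
#' count used by [posterior_K()] refers to subjects.
#'
#' Empty classes draw their parameters from the prior. The allocation
#' step can alternatively condition on the current random-effect draws
#' (`marginal_alloc = FALSE`); the two schemes target the same posterior
#' and the conditional variant is retained as a cross-check of the
#' marginalization algebra.
#'
#' @param data A `"longitudinal_dataset"` or a long-format data frame with
#'   columns `subject_id`, `time`, `y` and any covariates named in the
#'   model.
#' @param model A [growth_model_spec()].
#' @param prior A [growth_prior()]. A warning is raised when
#'   `prior$alpha >= model$d / 2`.
#' @param config An [mcmc_config()].
#' @param marginal_alloc Integrate random effects out in the allocation
#'   step (default) or condition on the current draws?
#' @param init `"spread"` (default) starts the class intercepts at
#'   quantiles of the per-subject mean response; `"common"` starts every
#'   class at the pooled mean so classes differentiate during burn-in.
#' @param share_re_cov Pool the random-effect covariance across classes?
#'   Defaults to `TRUE` for two or more random terms and `FALSE` for a
#'   single random intercept. An unstructured covariance updated per
#'   class lets a component shrink its covariance onto one or two
#'   subjects, and such overfitted singleton components are sticky; with
#'   the pooled update the empty-class count concentrates on the true
#'   number of classes. The dimension count `d` used for the
#'   `alpha < d/2` rule still follows the generating model.
#' @return An object of class `"growth_draws"` with per-iteration
#'   `lambda`, `theta` (class-specific fixed effects, columns grouped by
#'   class), `gamma`, `Sigma` (upper-triangle entries per class),
#'   `resid_var`, subject occupancy `counts`, marginal `loglik_obs`, and
#'   optionally subject allocations `z`.
#' @examples
#' d <- simulate_growth(mixture_scenario("B2"), seed = 1)
#' spec <- growth_model_spec(class_specific = "intercept", common = "time",
#'                           random = "intercept")
#' fit <- run_gibbs_growth(d, spec, growth_prior(alpha = 0.5),
#'                         mcmc_config(K_max = 10, n_iter = 300,
#'                                     burn_in = 100, seed = 1))
#' posterior_K(fit, psi = 0.05)
#' @export
run_gibbs_growth <- function(data, model, prior, config,
                             marginal_alloc = TRUE,
                             init = c("spread", "common"),
                             share_re_cov = NULL) {
  init <- match.arg(init)
  if (is.null(share_re_cov)) share_re_cov <- length(model$random) >= 2L
  stopifnot(inherits(model, "growth_model_spec"),
            inherits(prior, "growth_prior"),
            inherits(config, "mcmc_config"))
  if (length(model$random) < 1L)
    stop("the Gibbs sampler requires at least one random term")
  des <- build_designs(data, model)
  ns <- length(des$subj_start) - 1L
  if (ns < 1L) stop("need at least one subject")
  if (prior$alpha >= model$d / 2)
    warning("alpha = ", prior$alpha, " is not below d/2 = ", model$d / 2,
            "; superfluous classes are not guaranteed to empty",
            call. = FALSE)
  res <- with_seed(config$seed,
    gibbs_growth_cpp(des$y, des$subj_start, des$X, des$W, des$Z,
                     config$K_max, prior$alpha, prior$fixed_effect_var,
                     prior$resid_shape, prior$resid_rate,
                     prior$re_scale, prior$re_df,
                     config$n_iter, config$burn_in,
                     config$store_z, marginal_alloc,
                     if (init == "spread") 0L else 1L, share_re_cov))
  res$N <- ns
  res$K_max <- config$K_max
  res$model <- model
  res$prior <- prior
  res$config <- config
  class(res) <- "growth_draws"
  res
}

#' @export
print.growth_draws <- function(x, ...) {
  cat("Overfitted growth mixture draws: K_max =", x$K_max,
      ", retained iterations =", nrow(x$lambda),
      ", subjects =", x$N, "\n")
  cat("  model d =", x$model$d, ", Dirichlet alpha =", x$prior$alpha, "\n")
  if (nrow(x$counts) > 0) {
    pk <- posterior_K(x, psi = 0)
    cat("  posterior mode of non-empty classes (psi = 0):", pk$mode, "\n")
  }
  invisible(x)
}
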