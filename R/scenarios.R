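#' Benchmark simulation scenarios
#'
#' Returns the generative truth for one of the built-in benchmark scenarios.
#' Scenarios "A1"--"A4" and "A_unequal" are univariate location-scale
#' Gaussian mixtures with n = 500 observations; scenarios "B1"--"B3" are
#' linear growth mixtures observed on 200 subjects at 6 equally spaced
#' occasions (times 0..5).
#'
#' * `A1`: homogeneous, K = 1, mean 1, SD 0.25.
#' * `A2`: K = 3, means (1, 2, 3), SDs 0.25, equal proportions (high
#'   separation).
#' * `A3`: as A2 with SDs 0.4 (moderate separation).
#' * `A4`: as A2 with SDs 0.7 (low separation; marginally unimodal).
#' * `A_unequal`: as A2 with proportions (0.475, 0.475, 0.05).
#' * `B1`: homogeneous growth curve, intercept 2, slope -0.2, random
#'   intercept SD 0.25 and random slope SD 0.025, residual SD 0.25.
#' * `B2`: K = 3 intercepts (1, 2, 3), common slope -0.2, random intercept
#'   SD 0.25 (no random slope), residual SD 0.25.
#' * `B3`: K = 3 intercepts (1, 2, 3) and slopes (-0.1, -0.2, -0.3), random
#'   intercept SD 0.25 and random slope SD 0.025, residual SD 0.25.
#'
#' @param name Scenario identifier, one of `"A1"`, `"A2"`, `"A3"`, `"A4"`,
#'   `"A_unequal"`, `"B1"`, `"B2"`, `"B3"`.
#' @return An object of class `"univariate_scenario"` (fields `K_true`,
#'   `means`, `sds`, `proportions`, `n`) or `"growth_scenario"` (fields
#'   `K_true`, `fixed_intercepts`, `fixed_slopes`, `re_cov`,
#'   `random_slope_on`, `common_slope`, `resid_sd`, `proportions`,
#'   `n_subjects`, `n_obs`, `time_grid`).
#' @examples
#' mixture_scenario("A2")
#' mixture_scenario("B3")
#' @export
mixture_scenario <- function(name) {
  valid <- c("A1", "A2", "A3", "A4", "A_unequal", "B1", "B2", "B3")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid names are: ", paste(valid, collapse = ", "))
  }
  if (name %in% c("A1", "A2", "A3", "A4", "A_unequal")) {
    sc <- switch(name,
      A1 = univariate_scenario(1L, means = 1, sds = 0.25,
                               proportions = 1, n = 500L),
      A2 = univariate_scenario(3L, means = c(1, 2, 3), sds = rep(0.25, 3),
                               proportions = rep(1, 3) / 3, n = 500L),
      A3 = univariate_scenario(3L, means = c(1, 2, 3), sds = rep(0.4, 3),
                               proportions = rep(1, 3) / 3, n = 500L),
      A4 = univariate_scenario(3L, means = c(1, 2, 3), sds = rep(0.7, 3),
                               proportions = rep(1, 3) / 3, n = 500L),
      A_unequal = univariate_scenario(3L, means = c(1, 2, 3),
                                      sds = rep(0.25, 3),
                                      proportions = c(0.475, 0.475, 0.05),
                                      n = 500L))
  } else {
    Sig <- diag(c(0.25^2, 0.025^2))
    sc <- switch(name,
      B1 = growth_scenario(1L, fixed_intercepts = 2, fixed_slopes = -0.2,
                           re_cov = Sig, proportions = 1),
      B2 = growth_scenario(3L, fixed_intercepts = c(1, 2, 3),
                           fixed_slopes = NULL, common_slope = -0.2,
                           re_cov = matrix(0.25^2), random_slope_on = FALSE,
                           proportions = rep(1, 3) / 3),
      B3 = growth_scenario(3L, fixed_intercepts = c(1, 2, 3),
                           fixed_slopes = c(-0.1, -0.2, -0.3),
                           re_cov = Sig, proportions = rep(1, 3) / 3))
  }
  sc$name <- name
  sc
}

#' Construct a univariate mixture scenario
#'
#' Generative truth for a location-scale mixture of univariate normals:
#' each observation draws a class from `proportions` and then a normal
#' deviate with the class mean and SD.
#'
#' @param K_true Number of classes.
#' @param means,sds Numeric vectors of class means and standard deviations,
#'   one entry per class.
#' @param proportions Class probabilities; must sum to 1.
#' @param n Number of observations to generate.
#' @return An object of class `"univariate_scenario"`.
#' @export
univariate_scenario <- function(K_true, means, sds, proportions, n) {
  K_true <- as.integer(K_true)
  stopifnot(K_true >= 1L)
  if (length(means) != K_true || length(sds) != K_true ||
      length(proportions) != K_true) {
    stop("means, sds and proportions must each have length K_true = ", K_true)
  }
  if (any(sds <= 0)) stop("sds must be strictly positive")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-12) {
    stop("proportions must be nonnegative and sum to 1")
  }
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  structure(list(K_true = K_true, means = as.numeric(means),
                 sds = as.numeric(sds),
                 proportions = as.numeric(proportions), n = n),
            class = "univariate_scenario")
}

#' Construct a growth mixture scenario
#'
#' Generative truth for a latent-class linear mixed model: subject i in
#' class j has responses
#' `y_it = theta_j0 + b_i0 + (theta_j1 + b_i1) * time_t + eps_it`,
#' with `(b_i0, b_i1) ~ N(0, re_cov)` and `eps_it ~ N(0, resid_sd^2)`.
#' When `random_slope_on = FALSE` the random slope is fixed at zero and
#' `re_cov` is the 1x1 variance of the random intercept; the fixed slope is
#' then the single `common_slope` shared by all classes.
#'
#' @param K_true Number of classes.
#' @param fixed_intercepts Class-specific fixed intercepts.
#' @param fixed_slopes Class-specific fixed slopes, or `NULL` when a common
#'   slope is used.
#' @param re_cov Random-effect covariance matrix (2x2, or 1x1 for a random
#'   intercept only); must be symmetric positive semi-definite.
#' @param random_slope_on Does each subject have a random slope?
#' @param common_slope Fixed slope shared by all classes (used when
#'   `fixed_slopes` is `NULL`).
#' @param resid_sd Residual standard deviation.
#' @param proportions Class probabilities; must sum to 1.
#' @param n_subjects,n_obs Number of subjects and observations per subject.
#' @param time_grid Measurement times, strictly increasing, length `n_obs`.
#' @return An object of class `"growth_scenario"`.
#' @export
growth_scenario <- function(K_true, fixed_intercepts, fixed_slopes = NULL,
                            re_cov, random_slope_on = TRUE,
                            common_slope = NULL, resid_sd = 0.25,
                            proportions, n_subjects = 200L, n_obs = 6L,
                            time_grid = seq_len(n_obs) - 1) {
  K_true <- as.integer(K_true)
  stopifnot(K_true >= 1L, length(fixed_intercepts) == K_true)
  if (is.null(fixed_slopes)) {
    if (is.null(common_slope)) stop("need fixed_slopes or common_slope")
  } else if (length(fixed_slopes) != K_true) {
    stop("fixed_slopes must have length K_true")
  }
  re_cov <- as.matrix(re_cov)
  if (!isSymmetric(unname(re_cov)) || any(eigen(re_cov, symmetric = TRUE,
                                          only.values = TRUE)$values < -1e-12))
    stop("re_cov must be symmetric positive semi-definite")
  if (random_slope_on && nrow(re_cov) != 2L)
    stop("re_cov must be 2x2 when the random slope is on")
  if (!random_slope_on && nrow(re_cov) != 1L)
    stop("re_cov must be 1x1 when the random slope is off")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-12)
    stop("proportions must be nonnegative and sum to 1")
  if (length(proportions) != K_true)
    stop("proportions must have length K_true")
  if (resid_sd < 0) stop("resid_sd must be nonnegative")
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) != n_obs || any(diff(time_grid) <= 0))
    stop("time_grid must be strictly increasing with length n_obs")
  structure(list(K_true = K_true,
                 fixed_intercepts = as.numeric(fixed_intercepts),
                 fixed_slopes = if (!is.null(fixed_slopes))
                   as.numeric(fixed_slopes),
                 re_cov = re_cov, random_slope_on = isTRUE(random_slope_on),
                 common_slope = if (!is.null(common_slope))
                   as.numeric(common_slope),
                 resid_sd = as.numeric(resid_sd),
                 proportions = as.numeric(proportions),
                 n_subjects = as.integer(n_subjects),
                 n_obs = as.integer(n_obs), time_grid = time_grid),
            class = "growth_scenario")
}

#' @export
print.univariate_scenario <- function(x, ...) {
  cat("Univariate Gaussian mixture scenario",
      if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat("  K_true:", x$K_true, " n:", x$n, "\n")
  cat("  means:      ", paste(format(x$means), collapse = " "), "\n")
  cat("  sds:        ", paste(format(x$sds), collapse = " "), "\n")
  cat("  proportions:", paste(format(x$proportions), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.growth_scenario <- function(x, ...) {
  cat("Growth mixture scenario", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "\n")
  cat("  K_true:", x$K_true, " subjects:", x$n_subjects,
      " obs/subject:", x$n_obs, "\n")
  cat("  intercepts:", paste(format(x$fixed_intercepts), collapse = " "), "\n")
  if (!is.null(x$fixed_slopes))
    cat("  slopes:    ", paste(format(x$fixed_slopes), collapse = " "), "\n")
  if (!is.null(x$common_slope))
    cat("  common slope:", format(x$common_slope), "\n")
  cat("  random slope:", x$random_slope_on, " resid_sd:", x$resid_sd, "\n")
  invisible(x)
}
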