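#' Maximum-likelihood fit of a univariate Gaussian mixture by EM
#'
#' Standard EM with responsibilities computed in log space. The first
#' start places the means at data quantiles; subsequent starts draw the
#' means from randomly chosen observations. A variance floor of
#' `1e-6 * var(y)` prevents the unbounded-likelihood degeneracy of
#' location-scale Gaussian mixtures (a component collapsing onto a
#' single observation).
#'
#' @param data A `"univariate_dataset"` or numeric vector.
#' @param K Number of components (>= 1).
#' @param n_starts Number of EM initializations; the best final log
#'   likelihood wins.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Optional seed for the random starts.
#' @return An object of class `"mle_fit"`: `K`, `proportions`, `means`,
#'   `variances`, maximized `loglik`, the per-iteration `loglik_trace` of
#'   the winning start, free-parameter count `g = 3K - 1`, `n`,
#'   `converged`, `n_starts`.
#' @examples
#' d <- simulate_univariate(mixture_scenario("A2"), seed = 1)
#' fit <- em_univariate(d, K = 3, seed = 1)
#' sort(fit$means)
#' @export
em_univariate <- function(data, K, n_starts = 10L, tol = 1e-6,
                          max_iter = 500L, seed = NULL) {
  y <- if (inherits(data, "univariate_dataset")) data$values
       else as.numeric(data)
  n <- length(y)
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  if (n <= K) stop("need more observations than components")
  floor_var <- 1e-6 * var(y)
  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      mu <- if (s == 1L) quantile(y, (seq_len(K) - 0.5) / K, names = FALSE)
            else sample(y, K)
      fit <- em_univariate_one(y, K, mu, rep(var(y), K), rep(1 / K, K),
                               tol, max_iter, floor_var)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
      if (K == 1L) break  # deterministic
    }
    structure(list(K = K, proportions = best$pi, means = best$mu,
                   variances = best$s2, loglik = best$loglik,
                   loglik_trace = best$trace, g = 3L * K - 1L, n = n,
                   converged = best$converged, n_starts = n_starts),
              class = "mle_fit")
  })
}

em_univariate_one <- function(y, K, mu, s2, pi_k, tol, max_iter, floor_var) {
  n <- length(y)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dev2 <- outer(y, mu, "-")^2
    logp <- rep(log(pi_k) - 0.5 * log(2 * pi * s2), each = n) -
      sweep(dev2, 2L, 2 * s2, "/")
    dim(logp) <- c(n, K)
    mrow <- logp[cbind(seq_len(n), max.col(logp))]
    p <- exp(logp - mrow)
    rs <- rowSums(p)
    ll <- sum(mrow + log(rs))
    trace <- c(trace, ll)
    resp <- p / rs
    w <- colSums(resp)
    pi_k <- w / n
    mu <- colSums(resp * y) / w
    s2 <- pmax(colSums(resp * (outer(y, mu, "-"))^2) / w, floor_var)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(pi = pi_k, mu = mu, s2 = s2, loglik = trace[length(trace)],
       trace = trace, converged = converged)
}

#' @export
print.mle_fit <- function(x, ...) {
  cat("Gaussian mixture MLE: K =", x$K, ", loglik =",
      format(x$loglik), ", g =", x$g,
      if (!x$converged) "(not converged)", "\n")
  invisible(x)
}

#' Bayesian information criterion
#'
#' `BIC = -2 * loglik + g * log(n)`; smaller is better.
#'
#' @param loglik Maximized log likelihood.
#' @param g Number of free parameters.
#' @param n Number of observations.
#' @return The BIC value.
#' @examples
#' bic(-100, g = 5, n = 500)
#' @export
bic <- function(loglik, g, n) {
  if (n < 1) stop("n must be at least 1")
  -2 * loglik + g * log(n)
}

#' Select the number of classes by BIC
#'
#' Fits the model at each candidate K by EM and returns the K minimizing
#' BIC, ties broken toward smaller K. For univariate mixtures
#' `g = 3K - 1` (K means, K variances, K - 1 free proportions); for
#' growth mixtures g counts class-specific fixed effects, class-specific
#' free covariance entries, common fixed effects, the residual variance,
#' and K - 1 proportions.
#'
#' @param data A `"univariate_dataset"`/numeric vector, or a
#'   `"longitudinal_dataset"`/long data frame when `model` is given.
#' @param K_range Candidate numbers of classes.
#' @param model A [growth_model_spec()] for longitudinal data; `NULL`
#'   selects the univariate fitter.
#' @param n_starts,tol,max_iter,seed Passed to the EM fitter.
#' @param bic_n For growth models, count `n` in the BIC penalty as the
#'   number of `"subjects"` (default; the statistical units of a
#'   latent-class mixed model, and the convention of the standard
#'   latent-class trajectory software) or as total observation `"rows"`.
#' @return A `"criterion_result"` with `selected_K`, `values_by_K` and
#'   the per-K fits in `fits`.
#' @export
select_K_bic <- function(data, K_range, model = NULL, n_starts = 10L,
                         tol = 1e-6, max_iter = 500L, seed = NULL,
                         bic_n = c("subjects", "rows")) {
  bic_n <- match.arg(bic_n)
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) < 1L) stop("empty K range")
  fits <- lapply(seq_along(K_range), function(i) {
    s <- if (is.null(seed)) NULL else seed + i
    if (is.null(model))
      em_univariate(data, K_range[i], n_starts = n_starts, tol = tol,
                    max_iter = max_iter, seed = s)
    else
      em_growth(data, K_range[i], model, n_starts = n_starts, tol = tol,
                max_iter = max_iter, seed = s)
  })
  vals <- vapply(fits, function(f) {
    n_pen <- if (!is.null(model) && bic_n == "subjects") f$n_subjects
             else f$n
    bic(f$loglik, f$g, n_pen)
  }, 0)
  names(vals) <- K_range
  structure(list(criterion = "BIC",
                 selected_K = K_range[which.min(vals)],
                 values_by_K = vals, fits = fits),
            class = "criterion_result")
}
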