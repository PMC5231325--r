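#' Specify the structure of a latent-class linear mixed model
#'
#' Terms are named design columns of the long-format data; the literal
#' name `"intercept"` denotes a constant column, and any other name must
#' match a column of the data (e.g. `"time"` or a covariate).
#' `class_specific` terms get one coefficient per latent class
#' (`theta_j`), `common` terms a single shared coefficient (`gamma`), and
#' `random` terms subject-level Gaussian random effects with a
#' class-specific covariance matrix. The derived count `d` of
#' class-specific parameters (fixed effects plus free covariance entries)
#' drives the sparse-Dirichlet validity threshold `alpha < d/2`.
#'
#' @param class_specific Character vector of class-specific fixed-effect
#'   terms.
#' @param common Character vector of common fixed-effect terms (may be
#'   empty).
#' @param random Character vector of random-effect terms (typically
#'   `"intercept"` or `c("intercept", "time")`; may be empty for a
#'   fixed-effects-only model, which the EM fitter accepts but the Gibbs
#'   sampler does not).
#' @return An object of class `"growth_model_spec"` with the term lists
#'   and the derived `d`.
#' @examples
#' # random intercept + slope, class-specific intercept and slope: d = 5
#' growth_model_spec(class_specific = c("intercept", "time"),
#'                   random = c("intercept", "time"))
#' # random intercept only, class-specific intercept, common slope: d = 2
#' growth_model_spec(class_specific = "intercept", common = "time",
#'                   random = "intercept")
#' @export
growth_model_spec <- function(class_specific = c("intercept", "time"),
                              common = character(),
                              random = c("intercept", "time")) {
  stopifnot(length(class_specific) >= 1L)
  if (any(duplicated(class_specific)) || any(duplicated(common)) ||
      any(duplicated(random)))
    stop("duplicated terms")
  if (length(intersect(class_specific, common)))
    stop("a term cannot be both class-specific and common")
  p <- length(class_specific)
  r <- length(random)
  d <- p + r * (r + 1L) / 2L
  structure(list(class_specific = class_specific, common = common,
                 random = random, d = as.integer(d)),
            class = "growth_model_spec")
}

#' @export
print.growth_model_spec <- function(x, ...) {
  cat("Latent-class linear mixed model:\n")
  cat("  class-specific:", paste(x$class_specific, collapse = ", "), "\n")
  if (length(x$common))
    cat("  common:        ", paste(x$common, collapse = ", "), "\n")
  cat("  random:        ", paste(x$random, collapse = ", "), "\n")
  cat("  class-specific parameters d =", x$d,
      " (sparse Dirichlet needs alpha <", x$d / 2, ")\n")
  invisible(x)
}

## Build the design matrices for a model spec from long-format data.
build_designs <- function(data, model) {
  df <- if (inherits(data, "longitudinal_dataset")) data$data else data
  need <- setdiff(unique(c(model$class_specific, model$common,
                           model$random)), "intercept")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("data lacks design columns: ", paste(missing_cols, collapse = ", "))
  ord <- order(df$subject_id)
  df <- df[ord, , drop = FALSE]
  ids <- df$subject_id
  subj_start <- c(0L, cumsum(table(factor(ids, levels = unique(ids)))))
  mk <- function(terms) {
    if (!length(terms)) return(matrix(0, nrow(df), 0))
    m <- vapply(terms, function(nm) if (nm == "intercept") rep(1, nrow(df))
                else as.numeric(df[[nm]]), numeric(nrow(df)))
    matrix(m, nrow = nrow(df), dimnames = list(NULL, terms))
  }
  list(y = as.numeric(df$y),
       subj_start = as.integer(subj_start),
       X = mk(model$class_specific),
       W = mk(model$common),
       Z = mk(model$random),
       subject_ids = unique(ids))
}

#' Subject-level allocation probabilities
#'
#' Posterior class-membership probabilities for one subject with the
#' random effects integrated out analytically:
#' `p_j` proportional to
#' `lambda_j * MVN(y_i | X_i theta_j + W_i gamma, Z_i Sigma_j Z_i' +
#' resid_var * I)`, normalized in log space.
#'
#' @param y Response vector of the subject.
#' @param X Class-specific design matrix of the subject (rows =
#'   observations).
#' @param W Common design matrix (may have zero columns).
#' @param Z Random-effect design matrix.
#' @param lambda Mixing proportions.
#' @param theta Matrix of class-specific fixed effects, one column per
#'   class.
#' @param gamma Common fixed effects (length `ncol(W)`).
#' @param Sigma List of class-specific random-effect covariance matrices.
#' @param resid_var Residual variance.
#' @return Probability vector over classes.
#' @export
subject_allocation_probs <- function(y, X, W, Z, lambda, theta, gamma,
                                     Sigma, resid_var) {
  K <- length(lambda)
  if (all(lambda == 0)) stop("all mixing proportions are zero")
  Tn <- length(y)
  logp <- numeric(K)
  for (k in seq_len(K)) {
    mu <- as.numeric(X %*% theta[, k])
    if (ncol(W) > 0) mu <- mu + as.numeric(W %*% gamma)
    V <- Z %*% Sigma[[k]] %*% t(Z) + diag(resid_var, Tn)
    ch <- tryCatch(chol(V), error = function(e)
      stop("singular marginal covariance for class ", k))
    e <- backsolve(ch, y - mu, transpose = TRUE)
    logp[k] <- log(lambda[k]) - 0.5 * (Tn * log(2 * pi)) -
      sum(log(diag(ch))) - 0.5 * sum(e^2)
  }
  logp <- logp - max(logp[is.finite(logp)])
  p <- exp(logp)
  p[!is.finite(p)] <- 0
  p / sum(p)
}
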