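## Dataset containers deliberately keep the simulated values and the
## generating class labels in separate fields: fitting code only ever
## receives the data, the labels are for evaluation.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Simulate a univariate mixture dataset
#'
#' Draws `scenario$n` observations from the location-scale Gaussian mixture
#' defined by the scenario: a class index is sampled from the class
#' proportions, then a normal deviate with the class mean and SD. The
#' generating labels are stored alongside the values for later evaluation
#' but are never used by any fitting function.
#'
#' @param scenario A [univariate_scenario()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return An object of class `"univariate_dataset"`: a list with `values`
#'   (numeric vector) and `true_labels` (integer vector of generating
#'   classes).
#' @examples
#' d <- simulate_univariate(mixture_scenario("A2"), seed = 1)
#' table(d$true_labels)
#' @export
simulate_univariate <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "univariate_scenario"))
  with_seed(seed, {
    z <- sample.int(scenario$K_true, scenario$n, replace = TRUE,
                    prob = scenario$proportions)
    y <- rnorm(scenario$n, mean = scenario$means[z], sd = scenario$sds[z])
    structure(list(values = y, true_labels = z),
              class = "univariate_dataset")
  })
}

#' Simulate a growth mixture dataset
#'
#' Per subject: a class is drawn from the scenario proportions, random
#' effects are drawn from `N(0, re_cov)` (intercept only when the random
#' slope is off), and responses on the time grid get independent Gaussian
#' residuals.
#'
#' @param scenario A [growth_scenario()].
#' @param seed Integer seed for exact reproducibility.
#' @return An object of class `"longitudinal_dataset"`: a list with `data`
#'   (long-format data frame with columns `subject_id`, `time`, `y`, plus
#'   any covariates) and `true_labels` (one generating class per subject).
#' @examples
#' d <- simulate_growth(mixture_scenario("B2"), seed = 1)
#' head(d$data)
#' @export
simulate_growth <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "growth_scenario"))
  with_seed(seed, {
    ns <- scenario$n_subjects
    Tn <- scenario$n_obs
    z <- sample.int(scenario$K_true, ns, replace = TRUE,
                    prob = scenario$proportions)
    ch <- chol_psd(scenario$re_cov)
    r <- nrow(scenario$re_cov)
    b <- matrix(rnorm(ns * r), ns, r) %*% ch   # rows ~ N(0, re_cov)
    int_j <- scenario$fixed_intercepts[z] + b[, 1L]
    slope_fixed <- if (is.null(scenario$fixed_slopes))
      rep(scenario$common_slope, ns) else scenario$fixed_slopes[z]
    slope_j <- slope_fixed + if (r >= 2L) b[, 2L] else 0
    tg <- scenario$time_grid
    y <- rep(int_j, each = Tn) + rep(slope_j, each = Tn) * rep(tg, ns) +
      rnorm(ns * Tn, sd = scenario$resid_sd)
    df <- data.frame(subject_id = rep(seq_len(ns), each = Tn),
                     time = rep(tg, ns), y = y)
    structure(list(data = df, true_labels = z),
              class = "longitudinal_dataset")
  })
}

## Cholesky-like factor that tolerates exactly singular (e.g. zero) PSD
## matrices: returns U with t(U) %*% U == X.
chol_psd <- function(X) {
  ev <- eigen(X, symmetric = TRUE)
  v <- pmax(ev$values, 0)
  t(ev$vectors %*% (t(ev$vectors) * sqrt(v)))
}

#' Append tail outliers to a univariate dataset
#'
#' Appends `k_per_tail` values at `min(values) - offset * sd(values)` and
#' `k_per_tail` values at `max(values) + offset * sd(values)`, emulating
#' contamination of a sample by a few extreme observations at each tail.
#' The appended observations are labelled `NA` in `true_labels` (they come
#' from no mixture class) and flagged in an `outlier` field.
#'
#' @param data A `"univariate_dataset"`.
#' @param k_per_tail Number of outliers to add at each tail; 0 returns the
#'   input unchanged.
#' @param offset Distance beyond the observed range, in multiples of the
#'   sample SD. The default of 5 SDs is unambiguously outlying.
#' @return A `"univariate_dataset"` with `2 * k_per_tail` extra values and
#'   a logical `outlier` flag per observation.
#' @export
add_tail_outliers <- function(data, k_per_tail, offset = 5) {
  stopifnot(inherits(data, "univariate_dataset"))
  if (length(data$values) == 0L) stop("empty dataset")
  k_per_tail <- as.integer(k_per_tail)
  if (k_per_tail < 0L) stop("k_per_tail must be nonnegative")
  if (k_per_tail == 0L) return(data)
  s <- sd(data$values)
  lo <- min(data$values) - offset * s
  hi <- max(data$values) + offset * s
  structure(list(
    values = c(data$values, rep(lo, k_per_tail), rep(hi, k_per_tail)),
    true_labels = c(data$true_labels, rep(NA_integer_, 2L * k_per_tail)),
    outlier = c(rep(FALSE, length(data$values)),
                rep(TRUE, 2L * k_per_tail))),
    class = "univariate_dataset")
}

#' @export
print.univariate_dataset <- function(x, ...) {
  cat("Univariate dataset:", length(x$values), "observations,",
      length(unique(x$true_labels[!is.na(x$true_labels)])),
      "generating classes\n")
  invisible(x)
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  cat("Longitudinal dataset:", length(x$true_labels), "subjects,",
      nrow(x$data), "rows,",
      length(unique(x$true_labels)), "generating classes\n")
  invisible(x)
}
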