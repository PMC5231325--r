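#' Configure a factorial latent-class selection experiment
#'
#' Bundles everything needed to reproduce one arm of the benchmark
#' simulation design: a scenario, a selection criterion, grids over the
#' Dirichlet hyperparameter and the empty-class cut-off, the prior
#' family, and the MCMC budget. Per-dataset seeds are derived from
#' `base_seed` by index, so interrupted runs can resume from a cache and
#' produce aggregates identical to an uninterrupted run.
#'
#' @param scenario A scenario name accepted by [mixture_scenario()], or a
#'   scenario object.
#' @param criterion One of `"rm"` (posterior mode of the non-empty class
#'   count), `"bic"`, `"dic3"`, `"dic4"`.
#' @param alpha_grid Dirichlet hyperparameters to sweep (ignored by
#'   `"bic"`).
#' @param psi_grid Empty-class cut-offs to sweep (criterion `"rm"` only).
#' @param prior_family `"vague"` or `"normal_gamma"` class-parameter
#'   priors (univariate scenarios only).
#' @param n_datasets Number of simulated datasets per arm.
#' @param mcmc An [mcmc_config()] giving `K_max`, iteration and burn-in
#'   budgets (its seed is overridden per dataset).
#' @param K_range Candidate K values for `"bic"`/`"dic3"`/`"dic4"`.
#' @param n_starts EM starts for `"bic"`.
#' @param model A [growth_model_spec()] for growth scenarios; when `NULL`
#'   the spec matching the scenario's generating model is used.
#' @param base_seed Base seed; dataset i uses `base_seed + i`.
#' @param cache_dir Optional directory for per-dataset result caching
#'   (JSON, via the jsonlite package).
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(scenario,
                              criterion = c("rm", "bic", "dic3", "dic4"),
                              alpha_grid = 0.1,
                              psi_grid = c(0, 0.01, 0.02, 0.05),
                              prior_family = c("vague", "normal_gamma"),
                              n_datasets = 20L,
                              mcmc = mcmc_config(K_max = 10L,
                                                 n_iter = 10000L,
                                                 burn_in = 2000L),
                              K_range = 1:6, n_starts = 10L,
                              model = NULL, base_seed = 1L,
                              cache_dir = NULL) {
  criterion <- match.arg(criterion)
  prior_family <- match.arg(prior_family)
  if (is.character(scenario)) scenario <- mixture_scenario(scenario)
  n_datasets <- as.integer(n_datasets)
  if (n_datasets < 1L) stop("n_datasets must be at least 1")
  if (criterion %in% c("rm", "dic3", "dic4") && any(alpha_grid <= 0))
    stop("all alpha values must be positive")
  if (inherits(scenario, "growth_scenario") && is.null(model))
    model <- default_growth_model(scenario)
  structure(list(scenario = scenario, criterion = criterion,
                 alpha_grid = alpha_grid, psi_grid = psi_grid,
                 prior_family = prior_family, n_datasets = n_datasets,
                 mcmc = mcmc, K_range = K_range, n_starts = n_starts,
                 model = model, base_seed = as.integer(base_seed),
                 cache_dir = cache_dir),
            class = "experiment_config")
}

## the analysis model matching each generating scenario
default_growth_model <- function(scenario) {
  if (scenario$random_slope_on)
    growth_model_spec(class_specific = c("intercept", "time"),
                      random = c("intercept", "time"))
  else
    growth_model_spec(class_specific = "intercept", common = "time",
                      random = "intercept")
}

#' Run a latent-class selection experiment
#'
#' Simulates `n_datasets` datasets from the configured scenario (dataset
#' i is seeded with `base_seed + i`), applies the configured criterion to
#' each, and aggregates the percentage of datasets selecting the true K
#' together with the modal selected K for every (alpha, psi) cell. A
#' failing arm is recorded as `NA` rather than aborting the experiment.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-arm progress?
#' @return A data frame of class `"success_table"` with columns
#'   `criterion`, `alpha`, `psi`, `success_pct`, `modal_K`, `n_datasets`,
#'   and the per-dataset selections in the attribute `"selections"`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  sc <- config$scenario
  K_true <- sc$K_true
  is_growth <- inherits(sc, "growth_scenario")
  alphas <- if (config$criterion == "bic") NA_real_ else config$alpha_grid
  psis <- if (config$criterion == "rm") config$psi_grid else NA_real_
  rows <- list()
  selections <- list()
  for (a in alphas) {
    ## selected K per dataset; for "rm" a matrix datasets x psi
    sel <- matrix(NA_integer_, config$n_datasets, length(psis))
    for (i in seq_len(config$n_datasets)) {
      res <- tryCatch(
        cached_selection(config, a, i, is_growth),
        error = function(e) {
          warning("arm alpha=", a, " dataset ", i, " failed: ",
                  conditionMessage(e), call. = FALSE)
          rep(NA_integer_, length(psis))
        })
      sel[i, ] <- res
      if (verbose)
        message("alpha=", a, " dataset ", i, ": ",
                paste(res, collapse = "/"))
    }
    for (j in seq_along(psis)) {
      sr <- success_rate(sel[!is.na(sel[, j]), j], K_true)
      rows[[length(rows) + 1L]] <-
        data.frame(criterion = toupper(config$criterion), alpha = a,
                   psi = psis[j], success_pct = sr$success_pct,
                   modal_K = sr$modal_K,
                   n_datasets = sum(!is.na(sel[, j])))
      selections[[paste(a, psis[j], sep = "_")]] <- sel[, j]
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "selections") <- selections
  attr(out, "K_true") <- K_true
  class(out) <- c("success_table", class(out))
  out
}

## one dataset: simulate, fit, select; cached as JSON when configured
cached_selection <- function(config, alpha, i, is_growth) {
  cache_file <- NULL
  if (!is.null(config$cache_dir) &&
      requireNamespace("jsonlite", quietly = TRUE)) {
    dir.create(config$cache_dir, showWarnings = FALSE, recursive = TRUE)
    nm <- if (!is.null(config$scenario$name)) config$scenario$name else "sc"
    cache_file <- file.path(config$cache_dir,
                            paste0(nm, "_", config$criterion, "_",
                                   alpha, "_", i, ".json"))
    if (file.exists(cache_file))
      return(as.integer(unlist(jsonlite::read_json(cache_file))))
  }
  data_seed <- config$base_seed + i
  fit_seed <- config$base_seed + i + 104729L
  sel <- selection_for_dataset(config, alpha, data_seed, fit_seed,
                               is_growth)
  if (!is.null(cache_file))
    jsonlite::write_json(sel, cache_file)
  sel
}

selection_for_dataset <- function(config, alpha, data_seed, fit_seed,
                                  is_growth) {
  sc <- config$scenario
  if (is_growth) {
    d <- simulate_growth(sc, seed = data_seed)
    if (config$criterion == "rm") {
      cfg <- mcmc_config(K_max = config$mcmc$K_max,
                         n_iter = config$mcmc$n_iter,
                         burn_in = config$mcmc$burn_in, seed = fit_seed)
      fit <- suppressWarnings(run_gibbs_growth(
        d, config$model, growth_prior(alpha = alpha), cfg))
      return(vapply(config$psi_grid, function(ps)
        posterior_K(fit, psi = ps)$mode, 0L))
    }
    if (config$criterion == "bic") {
      res <- select_K_bic(d, config$K_range, model = config$model,
                          n_starts = config$n_starts, seed = fit_seed)
      return(res$selected_K)
    }
    stop("DIC selection is implemented for univariate mixtures only")
  }
  d <- simulate_univariate(sc, seed = data_seed)
  if (config$criterion == "bic") {
    res <- select_K_bic(d, config$K_range, n_starts = config$n_starts,
                        seed = fit_seed)
    return(res$selected_K)
  }
  prior <- suppressWarnings(univariate_prior(
    alpha = alpha,
    mean_prior = if (config$prior_family == "vague") "vague"
                 else "normal_gamma",
    var_prior = if (config$prior_family == "vague") "uniform"
                else "hierarchical"))
  if (config$criterion == "rm") {
    cfg <- mcmc_config(K_max = config$mcmc$K_max,
                       n_iter = config$mcmc$n_iter,
                       burn_in = config$mcmc$burn_in, seed = fit_seed)
    fit <- run_gibbs_univariate(d, prior, cfg)
    return(vapply(config$psi_grid, function(ps)
      posterior_K(fit, psi = ps)$mode, 0L))
  }
  cfg <- mcmc_config(K_max = config$mcmc$K_max,
                     n_iter = config$mcmc$n_iter,
                     burn_in = config$mcmc$burn_in, seed = fit_seed)
  res <- select_K_by_dic(d, config$K_range, prior, cfg,
                         criterion = config$criterion)
  res$selected_K
}

#' Success rate and modal selected K
#'
#' @param selected Integer vector of selected K values, one per dataset.
#' @param K_true The generating number of classes.
#' @return List with `success_pct` (percentage of datasets selecting
#'   `K_true`) and `modal_K` (mode of the selections, ties toward the
#'   smaller K).
#' @examples
#' success_rate(c(1, 2, 3, 3), K_true = 3)
#' @export
success_rate <- function(selected, K_true) {
  if (length(selected) < 1L)
    return(list(success_pct = NA_real_, modal_K = NA_integer_))
  tab <- tabulate(selected, nbins = max(selected))
  list(success_pct = 100 * mean(selected == K_true),
       modal_K = as.integer(which.max(tab)))
}

#' Render a success table
#'
#' Formats each (alpha, psi) cell as `"P%(mode)"` -- the percentage of
#' datasets selecting the true K with the modal selected K in
#' parentheses.
#'
#' @param table A `"success_table"` from [run_experiment()].
#' @param format `"markdown"` or `"csv"`.
#' @return A character string (one table), invisibly also printed.
#' @export
render_table <- function(table, format = c("markdown", "csv")) {
  format <- match.arg(format)
  cell <- function(p, m) {
    if (is.na(p)) "-" else sprintf("%g%%(%d)", p, m)
  }
  df <- as.data.frame(table)
  cols <- if (all(is.na(df$psi))) unique(df$criterion)
          else paste0("psi=", unique(df$psi))
  alphas <- unique(df$alpha)
  mat <- matrix("-", length(alphas), length(cols),
                dimnames = list(format(alphas), cols))
  for (ri in seq_len(nrow(df))) {
    ci <- if (all(is.na(df$psi))) match(df$criterion[ri], unique(df$criterion))
          else match(df$psi[ri], unique(df$psi))
    mat[match(df$alpha[ri], alphas), ci] <-
      cell(df$success_pct[ri], df$modal_K[ri])
  }
  if (format == "csv") {
    lines <- c(paste(c("alpha", cols), collapse = ","),
               vapply(seq_len(nrow(mat)), function(i)
                 paste(c(rownames(mat)[i], mat[i, ]), collapse = ","), ""))
  } else {
    header <- paste0("| alpha | ", paste(cols, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", length(cols) + 1L),
                             collapse = "|"), "|")
    lines <- c(header, sep,
               vapply(seq_len(nrow(mat)), function(i)
                 paste0("| ", rownames(mat)[i], " | ",
                        paste(mat[i, ], collapse = " | "), " |"), ""))
  }
  paste(lines, collapse = "\n")
}
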