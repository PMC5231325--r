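#' Count non-empty mixture components at one iteration
#'
#' A component is declared empty at cut-off `psi` when its occupancy
#' fraction is at most `psi`:
#' `K = K_max - sum(I(N_j / N <= psi))`. With `psi = 0` only components
#' with exactly zero allocated units count as empty; the inequality is
#' non-strict throughout.
#'
#' @param occupancy Nonnegative occupancy counts, one per component.
#' @param N Total number of allocated units (observations, or subjects
#'   for longitudinal models).
#' @param psi Cut-off fraction in `[0, 1)`.
#' @return Integer number of non-empty components.
#' @examples
#' count_nonempty(c(95, 4, 1), N = 100, psi = 0.02)  # 2
#' count_nonempty(c(475, 475, 50), N = 1000, psi = 0.05)  # 2
#' @export
count_nonempty <- function(occupancy, N, psi = 0) {
  if (any(occupancy < 0)) stop("occupancy counts must be nonnegative")
  if (N <= 0) stop("N must be positive")
  if (psi < 0 || psi >= 1) stop("psi must be in [0, 1)")
  as.integer(sum(occupancy / N > psi))
}

#' Posterior distribution of the number of non-empty classes
#'
#' Applies [count_nonempty()] to the occupancy counts of every retained
#' MCMC iteration and tabulates the result. The number of latent classes
#' is estimated as the posterior mode, with ties broken toward the
#' smaller K (parsimony).
#'
#' @param draws A `"mixture_draws"` or `"growth_draws"` object, or a
#'   matrix of occupancy counts (iterations x components).
#' @param psi Cut-off fraction in `[0, 1)`.
#' @param N Total units; only needed when `draws` is a plain matrix.
#' @return An object of class `"class_count_posterior"`: list with
#'   `counts_by_K` (named vector over `1..K_max`), `mode`, `psi` and the
#'   number of retained iterations `M`.
#' @export
posterior_K <- function(draws, psi = 0, N = NULL) {
  if (inherits(draws, c("mixture_draws", "growth_draws"))) {
    occ <- draws$counts
    N <- draws$N
  } else {
    occ <- as.matrix(draws)
    if (is.null(N)) stop("N must be given for a plain occupancy matrix")
  }
  if (nrow(occ) < 1L) stop("no retained iterations")
  K_max <- ncol(occ)
  k_m <- rowSums(occ / N > psi)
  tab <- tabulate(k_m, nbins = K_max)
  names(tab) <- seq_len(K_max)
  mode_k <- which.max(tab)  # which.max takes the first (smallest K) on ties
  structure(list(counts_by_K = tab, mode = as.integer(mode_k),
                 psi = psi, M = nrow(occ)),
            class = "class_count_posterior")
}

#' @export
print.class_count_posterior <- function(x, ...) {
  cat("Posterior of the number of non-empty classes (psi =", x$psi,
      ",", x$M, "iterations):\n")
  nz <- x$counts_by_K[x$counts_by_K > 0]
  print(round(nz / x$M, 4))
  cat("mode:", x$mode, "\n")
  invisible(x)
}

#' Select the number of classes by the overfitted-mixture criterion
#'
#' Convenience wrapper returning a criterion result from fitted
#' overfitted-mixture draws: the selected K is the posterior mode of the
#' non-empty class count at cut-off `psi`.
#'
#' @param draws A `"mixture_draws"` or `"growth_draws"` object.
#' @param psi Cut-off fraction.
#' @return An object of class `"criterion_result"`: list with
#'   `criterion = "RM"`, `selected_K`, and the full `posterior` histogram
#'   for diagnostics.
#' @export
select_K_rm <- function(draws, psi = 0) {
  pk <- posterior_K(draws, psi = psi)
  structure(list(criterion = "RM", selected_K = pk$mode, psi = psi,
                 posterior = pk),
            class = "criterion_result")
}

#' @export
print.criterion_result <- function(x, ...) {
  cat("Criterion", x$criterion,
      if (!is.null(x$psi)) paste0("(psi = ", x$psi, ")"),
      ": selected K =", x$selected_K, "\n")
  if (!is.null(x$values_by_K)) {
    cat("values by K:\n")
    print(round(x$values_by_K, 2))
  }
  invisible(x)
}
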