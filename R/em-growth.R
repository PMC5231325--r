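#' Maximum-likelihood fit of a latent-class linear mixed model by EM
#'
#' EM over the subject class memberships, with the Gaussian random
#' effects integrated analytically in the E-step (subject likelihoods are
#' marginal multivariate normals) and treated as missing data in the
#' M-step, which therefore has closed forms: weighted least squares for
#' the fixed effects, weighted second moments of the conditional
#' random-effect distribution for the class covariances, and a pooled
#' residual moment for the error variance. Parameter blocks are updated
#' one at a time (ECM), so the observed-data log likelihood is
#' non-decreasing across iterations.
#'
#' Subjects sharing an identical design block (same times and covariate
#' values, the typical balanced-panel case) are processed as a group with
#' dense matrix operations, so balanced designs with hundreds of subjects
#' fit in well under a second.
#'
#' @param data A `"longitudinal_dataset"` or long-format data frame.
#' @param K Number of classes.
#' @param model A [growth_model_spec()] (its `random` set may be empty,
#'   giving a plain fixed-effects mixture).
#' @param n_starts Number of initializations (the first spreads class
#'   intercepts over subject-mean quantiles; later starts sample them).
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum ECM iterations per start.
#' @param seed Optional seed for the random starts.
#' @param share_re_cov Share one random-effect covariance matrix across
#'   classes (default, the convention of standard latent-class
#'   mixed-model software) or estimate one per class? Sharing also
#'   changes the free-parameter count `g` used by BIC.
#' @return An object of class `"mle_growth_fit"`: `K`, `proportions`,
#'   `theta` (p x K class-specific fixed effects), `gamma`, `Sigma`
#'   (list of class covariance matrices), `resid_var`, maximized
#'   `loglik`, `loglik_trace`, free-parameter count `g`, `n` (rows),
#'   `n_subjects`, `converged`.
#' @examples
#' d <- simulate_growth(mixture_scenario("B2"), seed = 1)
#' spec <- growth_model_spec(class_specific = "intercept", common = "time",
#'                           random = "intercept")
#' fit <- em_growth(d, K = 3, spec, n_starts = 2, seed = 1)
#' sort(fit$theta[1, ])
#' @export
em_growth <- function(data, K, model, n_starts = 10L, tol = 1e-6,
                      max_iter = 200L, seed = NULL, share_re_cov = TRUE) {
  stopifnot(inherits(model, "growth_model_spec"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  des <- build_designs(data, model)
  ns <- length(des$subj_start) - 1L
  if (ns <= K) stop("need more subjects than classes")
  pats <- split_patterns(des)
  p <- ncol(des$X); q <- ncol(des$W); r <- ncol(des$Z)

  ## pooled OLS for initial fixed effects
  XW <- cbind(des$X, des$W)
  beta0 <- qr.coef(qr(XW), des$y)
  beta0[is.na(beta0)] <- 0
  resid0 <- des$y - XW %*% beta0
  subj_resid_mean <- vapply(seq_len(ns), function(i) {
    a <- des$subj_start[i] + 1L; b <- des$subj_start[i + 1L]
    mean(resid0[a:b])
  }, 0)
  v0 <- max(var(subj_resid_mean), 1e-4)

  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      offs <- if (s == 1L)
        quantile(subj_resid_mean, (seq_len(K) - 0.5) / K, names = FALSE)
      else sample(subj_resid_mean, K)
      theta <- matrix(beta0[seq_len(p)], p, K)
      theta[1L, ] <- theta[1L, ] + offs
      gamma <- if (q > 0) beta0[p + seq_len(q)] else numeric(0)
      Sigma <- replicate(K, {
        S <- diag(max(v0 / 2, 1e-6), max(r, 1L))[seq_len(r), seq_len(r),
                                                 drop = FALSE]
        if (r >= 2L) for (dd in 2:r) S[dd, dd] <- S[dd, dd] / 100
        S
      }, simplify = FALSE)
      sig2 <- max(var(as.numeric(resid0)) / 2, 1e-8)
      fit <- em_growth_one(pats, K, theta, gamma, Sigma, sig2,
                           rep(1 / K, K), tol, max_iter, ns, share_re_cov)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
      if (K == 1L) break
    }
    n_cov_sets <- if (share_re_cov) 1L else K
    g <- K * p + n_cov_sets * (r * (r + 1L) / 2L) + q + 1L + (K - 1L)
    structure(list(K = K, proportions = best$pi, theta = best$theta,
                   gamma = best$gamma, Sigma = best$Sigma,
                   resid_var = best$sig2, loglik = best$loglik,
                   loglik_trace = best$trace, g = as.integer(g),
                   n = length(des$y), n_subjects = ns,
                   converged = best$converged),
              class = "mle_growth_fit")
  })
}

## group subjects by identical design blocks so the E-step vectorizes
split_patterns <- function(des) {
  ns <- length(des$subj_start) - 1L
  keys <- vapply(seq_len(ns), function(i) {
    a <- des$subj_start[i] + 1L; b <- des$subj_start[i + 1L]
    paste(signif(c(des$X[a:b, ], des$W[a:b, ], des$Z[a:b, ]), 12),
          collapse = ",")
  }, "")
  lapply(split(seq_len(ns), keys), function(idx) {
    a <- des$subj_start[idx[1L]] + 1L; b <- des$subj_start[idx[1L] + 1L]
    Tn <- b - a + 1L
    Y <- vapply(idx, function(i) {
      ai <- des$subj_start[i] + 1L
      des$y[ai:(ai + Tn - 1L)]
    }, numeric(Tn))
    list(X = des$X[a:b, , drop = FALSE], W = des$W[a:b, , drop = FALSE],
         Z = des$Z[a:b, , drop = FALSE],
         Y = matrix(Y, nrow = Tn), idx = idx, Tn = Tn)
  })
}

em_growth_one <- function(pats, K, theta, gamma, Sigma, sig2, pi_k,
                          tol, max_iter, ns, share_re_cov = FALSE) {
  p <- nrow(theta); r <- nrow(Sigma[[1L]])
  q <- length(gamma)
  n_rows <- sum(vapply(pats, function(g) g$Tn * length(g$idx), 0))
  ll_old <- -Inf; trace <- numeric(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## ---- E-step + sufficient statistics ----
    w_sum <- numeric(K)                       # sum_i w_ij
    ll <- 0
    es <- lapply(pats, function(g) {
      A <- g$Y - if (q > 0) as.numeric(g$W %*% gamma) else 0
      ng <- ncol(g$Y)
      logp <- matrix(0, K, ng)
      bhat <- vector("list", K); Cb <- vector("list", K)
      for (k in seq_len(K)) {
        E <- A - as.numeric(g$X %*% theta[, k])
        if (r > 0) {
          V <- g$Z %*% Sigma[[k]] %*% t(g$Z) + diag(sig2, g$Tn)
          ch <- chol(V)
          Q <- backsolve(ch, E, transpose = TRUE)
          logp[k, ] <- log(pi_k[k]) - 0.5 * g$Tn * log(2 * pi) -
            sum(log(diag(ch))) - 0.5 * colSums(Q^2)
          VinvE <- backsolve(ch, Q)
          bhat[[k]] <- Sigma[[k]] %*% (t(g$Z) %*% VinvE)   # r x ng
          Qz <- backsolve(ch, g$Z %*% Sigma[[k]], transpose = TRUE)
          Cb[[k]] <- Sigma[[k]] - crossprod(Qz)
        } else {
          logp[k, ] <- log(pi_k[k]) - 0.5 * g$Tn * log(2 * pi * sig2) -
            colSums(E^2) / (2 * sig2)
          bhat[[k]] <- matrix(0, 0, ng); Cb[[k]] <- matrix(0, 0, 0)
        }
      }
      mx <- apply(logp, 2L, max)
      pr <- exp(sweep(logp, 2L, mx))
      cs <- colSums(pr)
      ll <<- ll + sum(mx + log(cs))
      w <- sweep(pr, 2L, cs, "/")               # K x ng responsibilities
      w_sum <<- w_sum + rowSums(w)
      list(A = A, w = w, bhat = bhat, Cb = Cb)
    })
    trace <- c(trace, ll)

    ## ---- M-step (ECM; each block maximizes Q given the others) ----
    pi_k <- w_sum / ns
    ## class covariances and residual variance first (use current theta)
    if (r > 0) {
      Ssets <- lapply(seq_len(K), function(k) {
        S <- matrix(0, r, r)
        for (gi in seq_along(pats)) {
          e <- es[[gi]]
          w <- e$w[k, ]
          S <- S + e$bhat[[k]] %*% (w * t(e$bhat[[k]])) +
            sum(w) * e$Cb[[k]]
        }
        S
      })
      if (share_re_cov) {
        S <- Reduce(`+`, Ssets) / ns
        Sigma <- replicate(K, psd_project(S), simplify = FALSE)
      } else {
        for (k in seq_len(K))
          Sigma[[k]] <- psd_project(Ssets[[k]] / max(w_sum[k], 1e-12))
      }
    }
    rss <- 0
    for (gi in seq_along(pats)) {
      g <- pats[[gi]]; e <- es[[gi]]
      for (k in seq_len(K)) {
        Rk <- e$A - as.numeric(g$X %*% theta[, k])
        if (r > 0) Rk <- Rk - g$Z %*% e$bhat[[k]]
        w <- e$w[k, ]
        tr_term <- if (r > 0)
          sum(w) * sum(diag(crossprod(g$Z) %*% e$Cb[[k]])) else 0
        rss <- rss + sum(w * colSums(Rk^2)) + tr_term
      }
    }
    sig2 <- max(rss / n_rows, 1e-10)
    ## class-specific fixed effects
    for (k in seq_len(K)) {
      M1 <- matrix(0, p, p); m2 <- numeric(p)
      for (gi in seq_along(pats)) {
        g <- pats[[gi]]; e <- es[[gi]]
        w <- e$w[k, ]
        M1 <- M1 + sum(w) * crossprod(g$X)
        targ <- e$A
        if (r > 0) targ <- targ - g$Z %*% e$bhat[[k]]
        m2 <- m2 + as.numeric(t(g$X) %*% (targ %*% w))
      }
      theta[, k] <- solve(M1 + diag(1e-10, p), m2)
    }
    ## common fixed effects
    if (q > 0) {
      M1 <- matrix(0, q, q); m2 <- numeric(q)
      for (gi in seq_along(pats)) {
        g <- pats[[gi]]; e <- es[[gi]]
        ng <- ncol(g$Y)
        M1 <- M1 + ng * crossprod(g$W)
        for (k in seq_len(K)) {
          w <- e$w[k, ]
          targ <- g$Y - as.numeric(g$X %*% theta[, k])
          if (r > 0) targ <- targ - g$Z %*% e$bhat[[k]]
          m2 <- m2 + as.numeric(t(g$W) %*% (targ %*% w))
        }
      }
      gamma <- as.numeric(solve(M1 + diag(1e-10, q), m2))
    }
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(pi = pi_k, theta = theta, gamma = gamma, Sigma = Sigma, sig2 = sig2,
       loglik = trace[length(trace)], trace = trace, converged = converged)
}

psd_project <- function(S) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev$vectors %*% (pmax(ev$values, 1e-10) * t(ev$vectors))
}

#' @export
print.mle_growth_fit <- function(x, ...) {
  cat("Latent-class linear mixed model MLE: K =", x$K, ", loglik =",
      format(x$loglik), ", g =", x$g,
      if (!x$converged) "(not converged)", "\n")
  invisible(x)
}
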