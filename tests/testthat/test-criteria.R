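test_that("non-empty class counting follows the cut-off rule exactly", {
  expect_equal(count_nonempty(c(500, rep(0, 9)), 500, 0), 1L)
  expect_equal(count_nonempty(c(95, 4, 1), 100, 0.02), 2L)
  ## boundary: a class at exactly psi counts as empty (non-strict)
  expect_equal(count_nonempty(c(475, 475, 50), 1000, 0.05), 2L)
  expect_error(count_nonempty(c(-1, 2), 1, 0), "nonnegative")
  expect_error(count_nonempty(c(1, 2), 0, 0), "positive")
  expect_error(count_nonempty(c(1, 2), 3, 1), "psi")
})

test_that("counting matches a brute-force indicator sum on random draws", {
  brute <- function(occ, N, psi) {
    k <- length(occ)
    for (j in seq_along(occ)) if (occ[j] / N <= psi) k <- k - 1L
    k
  }
  set.seed(11)
  for (i in 1:2000) {
    occ <- rmultinom(1, size = sample(10:500, 1),
                     prob = rgamma(sample(2:10, 1), 0.5) + 1e-3)[, 1]
    N <- sum(occ)
    if (N == 0) next
    for (psi in c(0, 0.01, 0.02, 0.05)) {
      expect_identical(count_nonempty(occ, N, psi), brute(occ, N, psi))
    }
  }
})

test_that("the count is monotone in psi and permutation invariant", {
  set.seed(12)
  for (i in 1:200) {
    occ <- rmultinom(1, 300, rgamma(8, 0.3) + 1e-3)[, 1]
    ks <- vapply(c(0, 0.01, 0.02, 0.05, 0.2), count_nonempty,
                 0L, occupancy = occ, N = 300)
    expect_true(all(diff(ks) <= 0))
    perm <- sample(occ)
    expect_identical(count_nonempty(perm, 300, 0.02),
                     count_nonempty(occ, 300, 0.02))
  }
})

test_that("the posterior mode of K breaks ties toward the smaller K", {
  occ <- rbind(c(10, 10, 10, 0), c(15, 15, 0, 0))
  ## iterations with K = 3, 3, 3, 4 -> mode 3
  m <- rbind(c(10, 10, 10, 0), c(10, 10, 10, 0), c(10, 10, 10, 0),
             c(9, 9, 9, 3))
  expect_equal(posterior_K(m, psi = 0, N = 30)$mode, 3L)
  ## tie between 3 and 4 -> 3
  m2 <- rbind(c(10, 10, 10, 0), c(10, 10, 10, 0),
              c(9, 9, 9, 3), c(9, 9, 9, 3))
  pk <- posterior_K(m2, psi = 0, N = 30)
  expect_equal(pk$mode, 3L)
  expect_equal(sum(pk$counts_by_K), 4)
  ## constant occupancy concentrates on one K
  m3 <- matrix(rep(c(20, 10, 0), each = 5), 5)
  expect_equal(unname(posterior_K(m3, psi = 0, N = 30)$counts_by_K[2]), 5)
})

test_that("DIC3 collapses for degenerate chains and matches brute force", {
  d <- simulate_univariate(mixture_scenario("A1"), seed = 1)
  fit <- run_gibbs_univariate(d, univariate_prior(alpha = 0.1),
                              tiny_config(K_max = 2, n_iter = 1,
                                          burn_in = 50,
                                          store_obs_density = TRUE))
  ## M = 1: both terms collapse and DIC3 = -2 loglik_obs
  expect_equal(dic3(fit), -2 * fit$loglik_obs[1], tolerance = 1e-8)

  ## all-identical draws collapse the same way
  ll <- rep(-12.5, 4)
  lf <- matrix(rep(c(-3, -4.5, -5), each = 4), 4)
  expect_equal(dic3(ll, lf), -2 * -12.5, tolerance = 1e-12)

  ## M = 2 toy chain against direct summation
  y <- c(-0.5, 0.2, 1.1)
  lam <- rbind(c(0.4, 0.6), c(0.7, 0.3))
  mu <- rbind(c(0, 1), c(-0.2, 1.4))
  s2 <- rbind(c(1, 0.5), c(0.8, 0.6))
  lf <- rbind(mixture_logdens(y, lam[1, ], mu[1, ], s2[1, ]),
              mixture_logdens(y, lam[2, ], mu[2, ], s2[2, ]))
  ll <- rowSums(lf)
  direct <- -4 * mean(ll) + 2 * sum(log(colMeans(exp(lf))))
  expect_equal(dic3(ll, lf), direct, tolerance = 1e-10)
})

test_that("DIC4 matches a direct evaluation of its plug-in second term", {
  ## single iteration, hand-built draws object
  y <- c(0.1, -0.2, 0.05, 2.1, 1.9)
  z <- matrix(c(1L, 1L, 1L, 2L, 2L), 1)
  prior <- univariate_prior(alpha = 0.5)
  llc <- -7.3
  draws <- structure(list(z = z, y = y, K_max = 2L, prior = prior,
                          loglik_complete = llc, hyper = NULL),
                     class = "mixture_draws")
  ## independent computation of the conditional posterior means
  n1 <- 3; n2 <- 2
  lam_hat <- (0.5 + c(n1, n2)) / (2 * 0.5 + 5)
  ss <- c(sum((y[1:3] - mean(y[1:3]))^2), sum((y[4:5] - mean(y[4:5]))^2))
  s2_hat <- vapply(1:2, function(k) {
    n <- c(n1, n2)[k]
    g <- 10 * (seq_len(512) - 0.5) / 512
    w <- exp(-(n / 2) * log(g) - ss[k] / (2 * g) -
               max(-(n / 2) * log(g) - ss[k] / (2 * g)))
    sum(w * g) / sum(w)
  }, 0)
  mu_hat <- c(sum(y[1:3]), sum(y[4:5])) / s2_hat /
    (c(n1, n2) / s2_hat + 1 / 1000)
  t2 <- sum(log(lam_hat[z[1, ]]) +
              dnorm(y, mu_hat[z[1, ]], sqrt(s2_hat[z[1, ]]), log = TRUE))
  expect_equal(dic4(draws), -4 * llc + 2 * t2, tolerance = 1e-8)

  ## missing allocations raise an error
  bad <- structure(list(z = NULL, y = y, K_max = 2L, prior = prior,
                        loglik_complete = llc), class = "mixture_draws")
  expect_error(dic4(bad), "store_z")
})

test_that("DIC selection returns audited values and respects trivial
           ranges", {
  d <- simulate_univariate(mixture_scenario("A1"), seed = 2)
  cfg <- tiny_config(n_iter = 300, burn_in = 100)
  res <- select_K_by_dic(d, 1, univariate_prior(alpha = 0.3), cfg, "dic3")
  expect_equal(res$selected_K, 1L)
  expect_named(res$values_by_K, "1")

  res3 <- select_K_by_dic(d, 1:3, univariate_prior(alpha = 0.3), cfg,
                          "dic3")
  expect_length(res3$values_by_K, 3L)
  expect_equal(res3$selected_K,
               as.integer(names(which.min(res3$values_by_K))))
})

test_that("DIC4 prefers one class on homogeneous data", {
  ## scaled-down comparison on three datasets; majority selects K = 1
  sel <- vapply(1:3, function(s) {
    sc <- univariate_scenario(1, 1, 0.25, 1, 150)
    d <- simulate_univariate(sc, seed = s)
    cfg <- tiny_config(n_iter = 400, burn_in = 150, seed = s)
    select_K_by_dic(d, 1:2, univariate_prior(alpha = 0.1), cfg,
                    "dic4")$selected_K
  }, 0L)
  expect_gte(sum(sel == 1L), 2)
})

test_that("DIC3 finds the three well-separated classes", {
  d <- simulate_univariate(mixture_scenario("A2"), seed = 4)
  cfg <- tiny_config(n_iter = 500, burn_in = 200, seed = 4)
  res <- select_K_by_dic(d, 2:4, univariate_prior(alpha = 0.3), cfg,
                         "dic3")
  expect_equal(res$selected_K, 3L)
})

test_that("criterion results are label-permutation invariant", {
  ## permuting component labels consistently across iterations leaves
  ## DIC3 and the class-count posterior unchanged
  d <- simulate_univariate(mixture_scenario("A2"), seed = 6)
  fit <- run_gibbs_univariate(d, univariate_prior(alpha = 0.1),
                              tiny_config(n_iter = 50, burn_in = 50,
                                          store_obs_density = TRUE))
  perm <- sample(10)
  fit_p <- fit
  fit_p$lambda <- fit$lambda[, perm]
  fit_p$means <- fit$means[, perm]
  fit_p$variances <- fit$variances[, perm]
  fit_p$counts <- fit$counts[, perm]
  expect_equal(dic3(fit_p), dic3(fit))
  expect_equal(posterior_K(fit_p, 0.02)$counts_by_K,
               posterior_K(fit, 0.02)$counts_by_K)
})
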