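test_that("subject allocation probabilities match their oracles", {
  Tn <- 4
  X <- cbind(1, 0:3)
  W <- matrix(0, Tn, 0)
  Z <- cbind(rep(1, Tn))
  Sig <- list(matrix(0.04), matrix(0.04))
  ## identical classes: probabilities equal the weights
  y <- c(1, 0.9, 1.1, 1)
  th <- cbind(c(1, 0), c(1, 0))
  expect_equal(subject_allocation_probs(y, X, W, Z, c(0.3, 0.7), th,
                                        numeric(0), Sig, 0.01),
               c(0.3, 0.7))
  ## single class
  expect_equal(subject_allocation_probs(y, X, W, Z, 1, th[, 1, drop = FALSE],
                                        numeric(0), Sig[1], 0.01), 1)
  ## noise-free subject on the class-2 trajectory
  th2 <- cbind(c(0, 0), c(2, -0.3))
  y2 <- 2 - 0.3 * (0:3)
  p <- subject_allocation_probs(y2, X, W, Z, c(0.5, 0.5), th2, numeric(0),
                                list(matrix(1e-6), matrix(1e-6)), 1e-4)
  expect_gt(p[2], 0.999)
})

test_that("growth chain conserves subject occupancy and stays PD", {
  d <- simulate_growth(mixture_scenario("B3"), seed = 2)
  fit <- suppressWarnings(run_gibbs_growth(
    d, b3_model(), growth_prior(alpha = 2),
    tiny_config(n_iter = 200, burn_in = 50)))
  expect_equal(unname(rowSums(fit$counts)), rep(200L, 200))
  ## stored Sigma upper triangles (v11, v12, v22) per class: PD check
  for (k in 1:10) {
    v11 <- fit$Sigma[, (k - 1) * 3 + 1]
    v12 <- fit$Sigma[, (k - 1) * 3 + 2]
    v22 <- fit$Sigma[, (k - 1) * 3 + 3]
    expect_true(all(v11 > 0 & v22 > 0))
    expect_true(all(v11 * v22 - v12^2 > 0))
  }
  expect_true(all(fit$resid_var > 0))
})

test_that("growth sampler is deterministic under a fixed seed", {
  d <- simulate_growth(mixture_scenario("B2"), seed = 1)
  f1 <- suppressWarnings(run_gibbs_growth(d, b2_model(),
        growth_prior(alpha = 0.5), tiny_config(n_iter = 100, seed = 4)))
  f2 <- suppressWarnings(run_gibbs_growth(d, b2_model(),
        growth_prior(alpha = 0.5), tiny_config(n_iter = 100, seed = 4)))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$counts, f2$counts)
})

test_that("K_max = 1 reduces to a Bayesian linear mixed model", {
  d <- simulate_growth(mixture_scenario("B1"), seed = 7)
  fit <- suppressWarnings(run_gibbs_growth(
    d, b3_model(), growth_prior(alpha = 1),
    tiny_config(K_max = 1, n_iter = 2000, burn_in = 400, seed = 7)))
  th0 <- fit$theta[, 1]
  th1 <- fit$theta[, 2]
  expect_lt(abs(mean(th0) - 2), 3 * sd(th0))
  expect_lt(abs(mean(th1) - (-0.2)), 3 * sd(th1))
  expect_lt(abs(mean(fit$resid_var) - 0.0625), 3 * sd(fit$resid_var))
})

test_that("marginal and conditional allocation agree on the class count", {
  d <- simulate_growth(mixture_scenario("B2"), seed = 4)
  fm <- suppressWarnings(run_gibbs_growth(d, b2_model(),
        growth_prior(alpha = 0.5),
        tiny_config(n_iter = 1500, burn_in = 500, seed = 21),
        marginal_alloc = TRUE))
  fc <- suppressWarnings(run_gibbs_growth(d, b2_model(),
        growth_prior(alpha = 0.5),
        tiny_config(n_iter = 1500, burn_in = 500, seed = 22),
        marginal_alloc = FALSE))
  expect_equal(posterior_K(fm, psi = 0.05)$mode,
               posterior_K(fc, psi = 0.05)$mode)
})

test_that("common fixed effects are recovered", {
  ## B2's shared slope enters as a common design column
  d <- simulate_growth(mixture_scenario("B2"), seed = 9)
  fit <- suppressWarnings(run_gibbs_growth(d, b2_model(),
        growth_prior(alpha = 0.5),
        tiny_config(n_iter = 1500, burn_in = 500, seed = 9)))
  expect_lt(abs(mean(fit$gamma[, 1]) - (-0.2)), 3 * sd(fit$gamma[, 1]))
})

test_that("hemoglobin-style models with several common covariates run", {
  ## synthetic stand-in emulating the blood-donor trajectory model:
  ## class-specific intercept and donation-count slope, common age,
  ## season and time-since-previous-donation effects
  set.seed(31)
  ns <- 80; Tn <- 5
  cls <- sample(1:2, ns, replace = TRUE)
  age <- round(runif(ns, 18, 65))
  df <- do.call(rbind, lapply(seq_len(ns), function(i) {
    nody2 <- seq_len(Tn) - 1
    season <- rbinom(Tn, 1, 0.5)
    tspd <- runif(Tn, 0.15, 1)
    b0 <- rnorm(1, 0, 0.3)
    y <- c(9.2, 9.8)[cls[i]] + b0 + 0.005 * age[i] - 0.1 * season +
      0.2 * tspd + c(-0.05, -0.15)[cls[i]] * nody2 + rnorm(Tn, 0, 0.3)
    data.frame(subject_id = i, time = nody2, y = y, Age = age[i],
               Season = season, TSPD = tspd, NODY2 = nody2)
  }))
  model <- growth_model_spec(class_specific = c("intercept", "NODY2"),
                             common = c("Age", "Season", "TSPD"),
                             random = c("intercept", "NODY2"))
  expect_equal(model$d, 5L)
  fit <- suppressWarnings(run_gibbs_growth(
    df, model, growth_prior(alpha = 2),
    tiny_config(K_max = 6, n_iter = 600, burn_in = 200, seed = 2)))
  expect_equal(unname(rowSums(fit$counts)), rep(80L, 600))
  expect_equal(ncol(fit$gamma), 3L)
  pk <- posterior_K(fit, psi = 0.05)
  expect_gte(pk$mode, 1L)
  expect_lte(pk$mode, 6L)
})

test_that("degenerate growth inputs raise errors", {
  d <- simulate_growth(mixture_scenario("B2"), seed = 1)
  expect_error(run_gibbs_growth(d,
    growth_model_spec(class_specific = "intercept", common = "xx",
                      random = "intercept"),
    growth_prior(alpha = 0.5), tiny_config(n_iter = 10)),
    "design columns")
  m0 <- growth_model_spec(class_specific = "intercept", random = character())
  expect_error(run_gibbs_growth(d, m0, growth_prior(alpha = 0.5),
                                tiny_config(n_iter = 10)),
               "random term")
})
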