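## Conjugacy oracles for the individual Gibbs updates.

test_that("allocation full conditional matches direct density evaluation", {
  ## symmetry: identical components split the probability by weight
  expect_equal(allocation_full_conditional(0.3, c(.5, .5), c(1, 1), c(1, 1)),
               c(.5, .5))
  ## degenerate weight
  expect_equal(allocation_full_conditional(0.3, c(1, 0), c(1, 5), c(1, 1)),
               c(1, 0))
  ## direct normal-density oracle
  p <- allocation_full_conditional(1, c(.5, .5), c(1, 3), c(1, 1))
  expect_equal(p[1], dnorm(0) / (dnorm(0) + dnorm(2)))
  ## extreme observation: no underflow thanks to log-space computation
  p <- allocation_full_conditional(1e4, c(.5, .5), c(0, 1), c(1, 1))
  expect_equal(sum(p), 1)
  expect_error(allocation_full_conditional(1, c(0, 0), c(1, 2), c(1, 1)),
               "zero")
})

test_that("proportion draws follow the Dirichlet posterior moments", {
  set.seed(1)
  draws <- t(replicate(20000, sample_proportions(c(3, 1), alpha = 0.5)))
  expect_true(all(abs(rowSums(draws) - 1) < 1e-10))
  ## posterior mean of lambda_1 = 3.5/5; SE of the MC mean from Dirichlet var
  m <- 3.5 / 5
  v <- m * (1 - m) / 6
  expect_lt(abs(mean(draws[, 1]) - m), 3 * sqrt(v / 20000))

  ## no data: the prior is recovered
  set.seed(2)
  pr <- t(replicate(20000, sample_proportions(c(0, 0, 0), alpha = 2)))
  expect_lt(abs(mean(pr[, 2]) - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 7 / 20000))

  ## exchangeability under symmetric counts
  set.seed(3)
  sym <- t(replicate(20000, sample_proportions(c(5, 5), alpha = 0.1)))
  expect_lt(abs(mean(sym[, 1]) - 0.5), 0.01)

  ## tiny alpha: draws remain valid probabilities
  set.seed(4)
  tiny <- t(replicate(200, sample_proportions(rep(0, 10), alpha = 1e-5)))
  expect_true(all(is.finite(tiny)))
  expect_true(all(abs(rowSums(tiny) - 1) < 1e-9))

  expect_error(sample_proportions(c(1, 2), alpha = 0), "positive")
  expect_error(sample_proportions(c(-1, 2), alpha = 1), "nonnegative")
})

test_that("mean draws follow the conjugate normal full conditional", {
  prior <- univariate_prior(alpha = 0.1)
  set.seed(1)
  y <- rnorm(2000, mean = 3, sd = 0.5)
  z <- rep(1L, 2000)
  v <- 0.25
  ## closed form with prior N(0, 1000)
  prec <- 2000 / v + 1 / 1000
  mpost <- (sum(y) / v) / prec
  draws <- replicate(4000, sample_means(y, z, variances = v, prior)[1])
  expect_lt(abs(mean(draws) - mpost), 3 * sqrt(1 / prec / 4000) + 1e-3)
  expect_lt(abs(sd(draws) - sqrt(1 / prec)) / sqrt(1 / prec), 0.1)

  ## empty second class reverts to the prior
  set.seed(2)
  emp <- replicate(4000, sample_means(y, z, variances = c(v, v), prior)[2])
  expect_lt(abs(mean(emp)), 3 * sqrt(1000 / 4000))
  expect_lt(abs(sd(emp) - sqrt(1000)) / sqrt(1000), 0.1)

  ## a huge prior variance approximates the MLE
  flat <- univariate_prior(alpha = 0.1, var0 = 1e12)
  set.seed(3)
  fl <- replicate(2000, sample_means(y, z, variances = v, flat)[1])
  expect_lt(abs(mean(fl) - mean(y)), 3 * sqrt(v / 2000 / 2000) + 1e-3)
})

test_that("variance draws follow their full conditionals", {
  prior <- univariate_prior(alpha = 0.1)  # uniform(0, 10) on sigma^2
  set.seed(1)
  y <- rnorm(10000, mean = 1, sd = 0.25)
  z <- rep(1L, 10000)
  draws <- replicate(2000, sample_variances(y, z, means = 1, prior)[1])
  expect_true(all(draws > 0 & draws < 10))
  ## conditional is inverse-gamma(n/2 - 1, ss/2); compare to its mean
  ss <- sum((y - 1)^2)
  a <- 10000 / 2 - 1
  m <- (ss / 2) / (a - 1)
  s <- sqrt((ss / 2)^2 / ((a - 1)^2 * (a - 2)))
  expect_lt(abs(mean(draws) - m), 3 * s / sqrt(2000) + 1e-4)
  expect_lt(abs(m - 0.0625), 3 * s)  # truth from a 0.25-SD class

  ## empty class under the uniform prior is uniform on (0, 10)
  set.seed(2)
  emp <- replicate(4000, sample_variances(y, z, means = c(1, 0), prior)[2])
  expect_lt(abs(mean(emp) - 5), 3 * sqrt(100 / 12 / 4000))

  ## hierarchical prior: empty class precision ~ Gamma(beta1, C0)
  hprior <- univariate_prior(alpha = 0.1, var_prior = "hierarchical")
  hs <- list(C0 = 2)
  set.seed(3)
  hemp <- replicate(20000,
    1 / sample_variances(y, z, means = c(1, 0), hprior, hs)[2])
  expect_lt(abs(mean(hemp) - 1.25 / 2), 3 * sqrt(1.25 / 4 / 20000))
})

test_that("hyperparameter draws follow their conjugate posteriors", {
  prior <- univariate_prior(alpha = 0.1, mean_prior = "normal_gamma",
                            var_prior = "hierarchical")
  ds <- list(m0 = 0.5, R = 4)
  hs <- list(b0 = 0.2, eta = 0.5, C0 = 1, R = 4)
  means <- c(1, 2, 3)
  vars <- c(0.1, 0.2, 0.3)
  ## b0 | means: closed-form conditional given eta in hs
  v_mu <- hs$eta * ds$R^2
  prec <- prior$M0_inv + 3 / v_mu
  mpost <- (ds$m0 * prior$M0_inv + sum(means) / v_mu) / prec
  set.seed(1)
  b0s <- replicate(4000,
    update_hyperparameters(means, vars, prior, ds, hs)$b0)
  expect_lt(abs(mean(b0s) - mpost), 3 * sqrt(1 / prec / 4000))
  expect_lt(abs(sd(b0s) - sqrt(1 / prec)) / sqrt(1 / prec), 0.1)

  ## C0 | precisions: Gamma(eps1 + K beta1, 20/R^2 + sum(1/sig2))
  shape <- prior$eps1 + 3 * prior$beta1
  rate <- 20 / ds$R^2 + sum(1 / vars)
  set.seed(2)
  c0s <- replicate(4000,
    update_hyperparameters(means, vars, prior, ds, hs)$C0)
  expect_lt(abs(mean(c0s) - shape / rate),
            3 * sqrt(shape / rate^2 / 4000))

  ## means clustered tightly: eta's conditional rate approaches nu2, so
  ## draws approach the Gamma(nu1 + K/2, nu2) moments
  set.seed(3)
  etas <- replicate(8000,
    update_hyperparameters(rep(0.5, 3), vars, prior,
                           list(m0 = 0.5, R = 1e6), hs)$eta)
  shape_eta <- prior$nu1 + 3 / 2
  expect_lt(abs(mean(etas) - shape_eta / prior$nu2),
            3 * sqrt(shape_eta / prior$nu2^2 / 8000) + 0.02)

  expect_error(update_hyperparameters(means, vars, prior,
                                      list(m0 = 0, R = 0), hs),
               "range")
})
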