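test_that("built-in scenarios carry the benchmark parameterizations", {
  a2 <- mixture_scenario("A2")
  expect_equal(a2$K_true, 3L)
  expect_equal(a2$means, c(1, 2, 3))
  expect_equal(a2$sds, rep(0.25, 3))
  expect_equal(a2$proportions, rep(1, 3) / 3)
  expect_equal(a2$n, 500L)

  a1 <- mixture_scenario("A1")
  expect_equal(a1$K_true, 1L)
  expect_equal(a1$means, 1)
  expect_equal(a1$sds, 0.25)

  expect_equal(mixture_scenario("A3")$sds, rep(0.4, 3))
  expect_equal(mixture_scenario("A4")$sds, rep(0.7, 3))
  expect_equal(mixture_scenario("A_unequal")$proportions,
               c(0.475, 0.475, 0.05))

  b1 <- mixture_scenario("B1")
  expect_equal(b1$fixed_intercepts, 2)
  expect_equal(b1$fixed_slopes, -0.2)
  expect_equal(b1$re_cov, diag(c(0.25^2, 0.025^2)))
  expect_equal(b1$resid_sd, 0.25)
  expect_equal(b1$n_subjects, 200L)
  expect_equal(b1$n_obs, 6L)

  b2 <- mixture_scenario("B2")
  expect_equal(b2$fixed_intercepts, c(1, 2, 3))
  expect_null(b2$fixed_slopes)
  expect_equal(b2$common_slope, -0.2)
  expect_false(b2$random_slope_on)
  expect_equal(b2$re_cov, matrix(0.25^2))

  b3 <- mixture_scenario("B3")
  expect_equal(b3$fixed_slopes, c(-0.1, -0.2, -0.3))

  expect_error(mixture_scenario("A9"), "valid names")
})

test_that("scenario constructors validate their invariants", {
  expect_error(univariate_scenario(2, means = 1, sds = c(1, 1),
                                   proportions = c(.5, .5), n = 10),
               "length")
  expect_error(univariate_scenario(2, means = c(1, 2), sds = c(1, -1),
                                   proportions = c(.5, .5), n = 10),
               "positive")
  expect_error(univariate_scenario(2, means = c(1, 2), sds = c(1, 1),
                                   proportions = c(.6, .6), n = 10),
               "sum to 1")
  expect_error(growth_scenario(1, fixed_intercepts = 0, fixed_slopes = 0,
                               re_cov = matrix(c(1, 2, 2, 1), 2),
                               proportions = 1),
               "semi-definite")
  expect_error(growth_scenario(1, fixed_intercepts = 0, fixed_slopes = 0,
                               re_cov = diag(2), proportions = 1,
                               time_grid = c(0, 0, 1, 2, 3, 4)),
               "increasing")
})

test_that("univariate simulation is reproducible and respects the truth", {
  sc <- mixture_scenario("A2")
  d1 <- simulate_univariate(sc, seed = 7)
  d2 <- simulate_univariate(sc, seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_univariate(sc, seed = 8)
  expect_false(identical(d1$values, d3$values))
  expect_length(d1$values, 500L)
  expect_length(d1$true_labels, 500L)

  expect_true(all(simulate_univariate(mixture_scenario("A1"),
                                      seed = 1)$true_labels == 1L))
})

test_that("large-sample moments match the generating mixture", {
  sc <- univariate_scenario(3, means = c(1, 2, 3), sds = rep(0.25, 3),
                            proportions = rep(1, 3) / 3, n = 100000L)
  d <- simulate_univariate(sc, seed = 42)
  ## population mean 2, variance = E[sig^2] + Var(mu)
  pop_var <- mean(sc$sds^2) + mean((sc$means - 2)^2)
  se <- sqrt(pop_var / sc$n)
  expect_lt(abs(mean(d$values) - 2), 3 * se)
  expect_lt(abs(var(d$values) - pop_var), 4 * pop_var / sqrt(sc$n) * 3)
  ## class frequencies consistent with the proportions
  gof <- chisq.test(tabulate(d$true_labels, 3), p = sc$proportions)
  expect_gt(gof$p.value, 0.001)
})

test_that("growth simulation matches its generating model", {
  sc <- mixture_scenario("B2")
  d1 <- simulate_growth(sc, seed = 3)
  d2 <- simulate_growth(sc, seed = 3)
  expect_identical(d1, d2)
  expect_equal(nrow(d1$data), 200L * 6L)
  expect_length(d1$true_labels, 200L)

  ## noise-free limit: responses lie exactly on the class line
  sc0 <- growth_scenario(1, fixed_intercepts = 2, fixed_slopes = NULL,
                         common_slope = -0.2, re_cov = matrix(0),
                         random_slope_on = FALSE, resid_sd = 0,
                         proportions = 1, n_subjects = 5, n_obs = 6)
  d0 <- simulate_growth(sc0, seed = 1)
  expect_equal(d0$data$y, 2 - 0.2 * d0$data$time, tolerance = 1e-12)

  ## per-class subject-mean intercepts near (1, 2, 3) for many subjects
  big <- growth_scenario(3, fixed_intercepts = c(1, 2, 3),
                         fixed_slopes = NULL, common_slope = -0.2,
                         re_cov = matrix(0.25^2), random_slope_on = FALSE,
                         proportions = rep(1, 3) / 3, n_subjects = 3000)
  db <- simulate_growth(big, seed = 5)
  ## detrended subject means estimate the class intercepts
  resid <- db$data$y + 0.2 * db$data$time
  sm <- tapply(resid, db$data$subject_id, mean)
  cls <- tapply(sm, db$true_labels, mean)
  expect_equal(as.numeric(cls), c(1, 2, 3), tolerance = 0.05)
})

test_that("tail outliers are appended outside the observed range", {
  d <- simulate_univariate(univariate_scenario(1, 1, 0.25, 1, 196),
                           seed = 2)
  expect_identical(add_tail_outliers(d, 0), d)
  out <- add_tail_outliers(d, 2)
  expect_length(out$values, 200L)
  expect_true(all(out$values[197:198] < min(d$values)))
  expect_true(all(out$values[199:200] > max(d$values)))
  expect_true(all(is.na(out$true_labels[197:200])))
  expect_equal(sum(out$outlier), 4L)
  empty <- structure(list(values = numeric(0), true_labels = integer(0)),
                     class = "univariate_dataset")
  expect_error(add_tail_outliers(empty, 1), "empty")
})

test_that("datasets round-trip through CSV with truth sidecars", {
  tmp <- withr::local_tempdir()
  d <- simulate_univariate(mixture_scenario("A2"), seed = 1)
  write_dataset_csv(d, file.path(tmp, "y.csv"), file.path(tmp, "lab.csv"))
  back <- read_univariate_csv(file.path(tmp, "y.csv"),
                              file.path(tmp, "lab.csv"))
  expect_equal(back$values, d$values, tolerance = 1e-12)
  expect_identical(back$true_labels, d$true_labels)

  g <- simulate_growth(mixture_scenario("B2"), seed = 1)
  write_dataset_csv(g, file.path(tmp, "g.csv"), file.path(tmp, "glab.csv"))
  gback <- read_longitudinal_csv(file.path(tmp, "g.csv"),
                                 file.path(tmp, "glab.csv"))
  expect_equal(gback$data$y, g$data$y, tolerance = 1e-12)
  expect_identical(gback$true_labels, g$true_labels)
})
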