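test_that("sampler recovers a standard normal target", {
  ch <- metropolis_sample(function(x) -sum(x^2) / 2, c(mu = 0.5),
                          n_chains = 4, n_steps = 2500, seed = 3)
  x <- pooled_samples(ch, "mu")
  expect_lt(abs(mean(x)), 0.1)
  expect_lt(abs(sd(x) - 1), 0.1)
  expect_true(all(ch$rhat < 1.05))
  expect_true(all(ch$acceptance > 0.1 & ch$acceptance < 0.6))
})

test_that("sampler matches the beta-binomial conjugate posterior", {
  # Beta(2,2) prior, 7 successes in 10 trials -> posterior Beta(9,5),
  # mean 9/14; sampled on the logit scale with the Jacobian
  logpost <- function(z) {
    p <- 1 / (1 + exp(-z))
    7 * log(p) + 3 * log(1 - p) +          # binomial kernel
      dbeta(p, 2, 2, log = TRUE) + log(p * (1 - p))
  }
  ch <- metropolis_sample(logpost, c(z = 0), n_chains = 4, n_steps = 3000,
                          seed = 11)
  p <- 1 / (1 + exp(-pooled_samples(ch, "z")))
  expect_lt(abs(mean(p) - 9 / 14), 0.01)
  post_sd <- sqrt(9 * 5 / (14^2 * 15))
  expect_lt(abs(sd(p) - post_sd), 0.02)
})

test_that("identical seeds give bitwise-identical chains", {
  lp <- function(x) -sum((x - c(1, -1))^2)
  a <- metropolis_sample(lp, c(u = 0, v = 0), n_chains = 2, n_steps = 400,
                         seed = 7)
  b <- metropolis_sample(lp, c(u = 0, v = 0), n_chains = 2, n_steps = 400,
                         seed = 7)
  expect_identical(a$samples, b$samples)
  d <- metropolis_sample(lp, c(u = 0, v = 0), n_chains = 2, n_steps = 400,
                         seed = 8)
  expect_false(identical(a$samples, d$samples))
})

test_that("covariance adaptation handles correlated targets", {
  S <- matrix(c(1, 0.97, 0.97, 1), 2)
  Si <- solve(S)
  lp <- function(x) -0.5 * drop(t(x) %*% Si %*% x)
  ch <- metropolis_sample(lp, c(a = 0, b = 0), n_chains = 4, n_steps = 3000,
                          seed = 5)
  x <- pooled_samples(ch)
  expect_lt(abs(cor(x[, 1], x[, 2]) - 0.97), 0.03)
  expect_true(all(ch$rhat < 1.1))
})

test_that("non-finite starting density is an error", {
  expect_error(metropolis_sample(function(x) -Inf, c(a = 0), n_chains = 2,
                                 n_steps = 100, seed = 1), "finite")
})

test_that("sequential chaining: a no-information stage reproduces the prior stage", {
  # stage 2 re-samples the same parameter with only its carried prior
  df <- cow_table("2014-01-01", 4,
                  as.character(seq(as.Date("2014-01-01"),
                                   as.Date("2017-01-01"), by = 30)),
                  censored_on = "2017-01-01")
  cc <- make_cc_data(df)
  stages <- list(
    A = model_stage("A", "cc", free = c("a2", "a3", "b3"),
                    fixed = c(a1 = 0, b1 = 1),
                    init = c(a2 = 0.1, a3 = 0.02, b3 = 0.3)),
    B = model_stage("B", "cc", free = c("a2", "a3", "b3"),
                    fixed = c(a1 = 0, b1 = 1), prior_from = "A"))
  # stage B refits the same tiny dataset; with the carried prior its
  # posterior mean should stay within a posterior sd of stage A's
  fits <- sequential_fit(stages, list(cc = cc), seed = 2, n_chains = 2,
                         n_steps = 800, burn_steps = 800)
  za <- colMeans(pooled_samples(fits$A$chains))
  zb <- colMeans(pooled_samples(fits$B$chains))
  sa <- apply(pooled_samples(fits$A$chains), 2, sd)
  expect_true(all(abs(za - zb) < sa))
})

test_that("unknown prior stage or missing init is a configuration error", {
  cc <- make_cc_data(cow_table("2014-01-01", 4,
                               c("2014-01-01", "2015-01-01"),
                               censored_on = "2015-01-01"))
  bad <- list(B = model_stage("B", "cc", free = "a2", fixed = c(a1 = 0, b1 = 1),
                              prior_from = "missing"))
  expect_error(sequential_fit(bad, list(cc = cc), seed = 1, n_chains = 1,
                              n_steps = 10), "unfitted stage")
  noinit <- list(A = model_stage("A", "cc", free = c("a2", "a3", "b3"),
                                 fixed = c(a1 = 0, b1 = 1)))
  expect_error(sequential_fit(noinit, list(cc = cc), seed = 1, n_chains = 1,
                              n_steps = 10), "no init")
})
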