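# Gamma-prior Bayesian estimation via Metropolis-Hastings.

test_that("log-posterior equals log prior plus data objective", {
  s <- il_fixture("rme_S1")
  th <- seq(0.5, 2.5, by = 0.25)
  # noninformative limit: difference from the log-likelihood is -log(theta)
  expect_equal(il_posterior(th, s) - il_loglik(th, s), -log(th),
               tolerance = 1e-12)
  # informative gamma(2, 3) prior, spacing source
  d <- il_posterior(th, s, prior = c(2, 3), source = "sp") -
    il_logspacing(th, s)
  expect_equal(d, (2 - 1) * log(th) - 3 * th, tolerance = 1e-12)
  expect_identical(il_posterior(-1, s), -Inf)
  expect_error(il_posterior(1, s, prior = c(-1, 0)), "nonnegative")
})

test_that("the posterior normalizes and its mode matches a grid maximizer", {
  s <- il_fixture("rme_S1")
  Z <- integrate(function(th) exp(il_posterior(th, s)), 0.01, 50)$value
  expect_true(is.finite(Z) && Z > 0)
  grid <- seq(0.2, 4, by = 1e-3)
  gmax <- grid[which.max(il_posterior(grid, s))]
  omax <- optimize(function(th) il_posterior(th, s), c(0.2, 4),
                   maximum = TRUE)$maximum
  expect_lt(abs(gmax - omax), 1e-3)
})

test_that("chain means match quadrature posterior means within Monte-Carlo error", {
  s <- il_fixture("rme_S1")
  for (source in c("lik", "sp")) {
    ch <- il_mh(s, source = source, n_iter = 12000, burn_in = 2000,
                proposal_scale = 1, seed = 31)
    q <- quad_post_mean(s, source = source)
    expect_lt(abs(mean(ch$draws) - q), 3 * bm_se(ch$draws))
  }
})

test_that("chains are reproducible and accept at the tuned rate", {
  s <- il_fixture("rme_S1")
  a <- il_mh(s, n_iter = 2000, burn_in = 500, seed = 5)
  b <- il_mh(s, n_iter = 2000, burn_in = 500, seed = 5)
  expect_identical(a$draws, b$draws)
  expect_true(all(a$draws > 0))
  expect_length(a$draws, 1500)
  # small-step proposal keeps acceptance high (reported band 85-99%)
  for (fx in c("rme_S1", "art_S1")) {
    ch <- il_mh(il_fixture(fx), n_iter = 5000, burn_in = 1000,
                proposal_scale = 0.25, seed = 8)
    expect_gt(ch$acceptance_rate, 0.85)
    expect_lt(ch$acceptance_rate, 0.99)
  }
})

test_that("squared-error summaries transform draws, not the point estimate", {
  s <- il_fixture("rme_S1")
  fit <- il_fit(s, method = "bayes_lf", t = 0.5, seed = 13,
                mcmc = mcmc_control(n_iter = 4000, burn_in = 1000))
  rf_draws <- vapply(fit$draws, function(th)
    pinvlindley(0.5, th, lower.tail = FALSE), numeric(1))
  expect_equal(fit$rf$est, mean(rf_draws), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    fit$rf$est, pinvlindley(0.5, fit$theta, lower.tail = FALSE),
    tolerance = 1e-6)))
  # equal-tailed interval contains the posterior median
  expect_gt(median(fit$draws), fit$ci[1])
  expect_lt(median(fit$draws), fit$ci[2])
})

test_that("informative priors shrink the estimate toward the prior mean", {
  set.seed(77)
  z <- rinvlindley(200, 0.5)
  mle <- il_fit(z, method = "mle")$theta
  post <- quad_post_mean(as_atipc(z), prior = c(93.156, 184.08))
  lohi <- sort(c(93.156 / 184.08, mle))
  expect_gt(post, lohi[1] - 1e-6)
  expect_lt(post, lohi[2] + 1e-6)
})

test_that("with flat prior and large n the Bayes point approaches the MLE", {
  set.seed(123)
  z <- rinvlindley(1000, 0.5)
  mle <- il_fit(z, method = "mle")$theta
  post <- quad_post_mean(as_atipc(z))
  expect_lt(abs(post - mle), 1e-3)
})

test_that("the potential scale reduction statistic behaves as a diagnostic", {
  x <- rnorm(1e4)
  expect_equal(gelman_rubin(list(x, x)), 1, tolerance = 1e-3)
  s <- il_fixture("rme_S1")
  ch1 <- il_mh(s, n_iter = 8000, burn_in = 2000, proposal_scale = 1, seed = 1)
  ch2 <- il_mh(s, n_iter = 8000, burn_in = 2000, proposal_scale = 1, seed = 2)
  expect_lt(gelman_rubin(list(ch1, ch2)), 1.05)
  # deliberately overdispersed short chains without burn-in
  b1 <- il_mh(s, n_iter = 150, burn_in = 0, init = 0.01, proposal_sd = 0.02,
              seed = 3)
  b2 <- il_mh(s, n_iter = 150, burn_in = 0, init = 100, proposal_sd = 0.02,
              seed = 4)
  expect_gt(gelman_rubin(list(b1, b2)), 1.1)
  expect_error(gelman_rubin(list(ch1)), "two chains")
  skip_if_not_installed("coda")
  # cross-check against an independent implementation
  mc <- coda::mcmc.list(coda::mcmc(ch1$draws), coda::mcmc(ch2$draws))
  expect_equal(gelman_rubin(list(ch1, ch2)),
               unname(coda::gelman.diag(mc, autoburnin = FALSE,
                                        transform = FALSE)$psrf[1, 1]),
               tolerance = 0.01)
})
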