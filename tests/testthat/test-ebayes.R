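# E-Bayesian estimation: hyperprior, Monte-Carlo double integral, intervals.

test_that("hyperprior draws have beta x uniform moments and support", {
  hp <- il_hyperprior(1e5, c(eps1 = 2, eps2 = 5, c = 0.8), seed = 1)
  expect_true(all(hp$a > 0 & hp$a < 1))
  expect_true(all(hp$b > 0 & hp$b < 0.8))
  se_a <- sqrt(2 * 5 / ((7)^2 * 8)) / sqrt(1e5)
  expect_lt(abs(mean(hp$a) - 2 / 7), 3 * se_a)
  expect_lt(abs(mean(hp$b) - 0.4), 3 * (0.8 / sqrt(12)) / sqrt(1e5))
  expect_identical(il_hyperprior(10, seed = 2), il_hyperprior(10, seed = 2))
  expect_error(il_hyperprior(5, c(-1, 1, 1)), "positive")
})

test_that("E-Bayes point is the average of the per-draw Bayes points", {
  s <- il_fixture("rme_S1")
  fit <- il_fit(s, method = "ebayes_lf", seed = 4,
                mcmc = mcmc_control(J = 12, inner_n_iter = 1200,
                                    inner_burn_in = 300))
  expect_equal(fit$theta, mean(fit$per_draw$theta_mean), tolerance = 1e-12)
  # marginalization consistency: inside the hull of the per-draw points
  expect_gte(fit$theta, min(fit$per_draw$theta_mean))
  expect_lte(fit$theta, max(fit$per_draw$theta_mean))
  # reproducibility
  fit2 <- il_fit(s, method = "ebayes_lf", seed = 4,
                 mcmc = mcmc_control(J = 12, inner_n_iter = 1200,
                                     inner_burn_in = 300))
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$ci, fit2$ci)
})

test_that("a degenerate hyperprior collapses E-Bayes onto the ordinary Bayes fit", {
  s <- il_fixture("rme_S1")
  a0 <- 0.5; M <- 2e4
  fit <- il_fit(s, method = "ebayes_lf",
                hyper = c(eps1 = a0 * M, eps2 = (1 - a0) * M, c = 1e-4),
                seed = 9,
                mcmc = mcmc_control(J = 24, inner_n_iter = 2500,
                                    inner_burn_in = 500, proposal_scale = 1))
  bayes <- quad_post_mean(s, prior = c(a0, 5e-5))
  se <- sd(fit$per_draw$theta_mean) / sqrt(nrow(fit$per_draw))
  expect_lt(abs(fit$theta - bayes), 3 * max(se, 5e-3))
})

test_that("Monte-Carlo E-Bayes matches nested quadrature on a coarse hyperparameter grid", {
  s <- il_fixture("rme_S1")
  hyper <- c(eps1 = 0.75, eps2 = 0.75, c = 1)
  for (source in c("lik", "sp")) {
    method <- if (source == "lik") "ebayes_lf" else "ebayes_sf"
    fit <- il_fit(s, method = method, hyper = hyper, seed = 17,
                  mcmc = mcmc_control(J = 60, inner_n_iter = 2500,
                                      inner_burn_in = 500,
                                      proposal_scale = 1))
    # midpoint product rule over (a, b) with beta x uniform weights
    na <- 16; nb <- 8
    agrid <- (seq_len(na) - 0.5) / na
    bgrid <- (seq_len(nb) - 0.5) / nb * hyper[["c"]]
    wa <- dbeta(agrid, hyper[["eps1"]], hyper[["eps2"]]) / na
    wa <- wa / sum(wa)
    quad <- 0
    for (i in seq_len(na)) for (j in seq_len(nb))
      quad <- quad + wa[i] / nb *
        quad_post_mean(s, prior = c(agrid[i], bgrid[j]), source = source)
    se <- sd(fit$per_draw$theta_mean) / sqrt(nrow(fit$per_draw))
    expect_lt(abs(fit$theta - quad), 3 * max(se, 5e-3))
  }
})

test_that("informative spacing-based Bayes beats plain ML accuracy under the first design", {
  # the elicited informative gamma prior concentrates near the true scale,
  # so the posterior-mean estimators dominate the MLE on every estimand
  res <- il_simstudy(n = 40, m = 20, scheme = rep(5, 4), tau = 0.5,
                     theta = 0.5, t = 0.1, reps = 50,
                     methods = c("mle", "bayes_sf"), seed = 2,
                     prior = c(93.47667, 189.0999),
                     mcmc = mcmc_control(n_iter = 3000, burn_in = 1000))
  rmse <- function(m, e) res$RMSE[res$method == m & res$estimand == e]
  for (e in c("theta", "rf", "hrf"))
    expect_lt(rmse("bayes_sf", e), rmse("mle", e))
})
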