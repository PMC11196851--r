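# E-Bayesian estimation ------------------------------------------------------
#
# The gamma prior's hyperparameters (a, b) are themselves random:
# a ~ beta(eps1, eps2) on (0, 1) and b ~ uniform(0, c), independent.  The
# E-Bayes estimator is the expectation of the ordinary Bayes estimator over
# this hyperprior, evaluated by Monte Carlo: J hyperprior draws, one
# Metropolis-Hastings chain per draw, and the average of the J posterior
# means.  Credible intervals pool the draws of all J chains, the Monte-Carlo
# analogue of mixing the posterior over the hyperprior.

#' Draw from the hyperprior on the gamma prior's parameters
#'
#' Independent draws \eqn{a_j \sim \mathrm{beta}(\epsilon_1,\epsilon_2)} and
#' \eqn{b_j \sim U(0, c)}.
#'
#' @param J number of draws.
#' @param hyper numeric `c(eps1, eps2, c)` with positive entries.
#' @param seed optional integer seed.
#' @return A data frame with columns `a` and `b` and `J` rows.
#' @examples
#' il_hyperprior(5, c(eps1 = 0.75, eps2 = 0.75, c = 1), seed = 1)
#' @export
il_hyperprior <- function(J, hyper = c(eps1 = 0.75, eps2 = 0.75, c = 1),
                          seed = NULL) {
  eps1 <- hyper[[1]]; eps2 <- hyper[[2]]; cc <- hyper[[3]]
  if (!(eps1 > 0 && eps2 > 0 && cc > 0))
    stop("hyperprior parameters must be positive", call. = FALSE)
  stopifnot(J >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(a = stats::rbeta(J, eps1, eps2),
             b = stats::runif(J, 0, cc))
}

.il_fit_ebayes <- function(sample, method, t, level, hyper, control, mcmc,
                           seed) {
  source <- if (method == "ebayes_lf") "lik" else "sp"
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  ab <- il_hyperprior(mcmc$J, hyper, seed = seed)
  # one frequentist initialization shared by all inner chains
  fr <- .il_fit_freq(sample, if (source == "lik") "lik" else "sp",
                     control = control)
  psd <- if (is.null(mcmc$proposal_sd)) mcmc$proposal_scale * fr$se
         else mcmc$proposal_sd
  per <- vector("list", mcmc$J)
  pooled <- vector("list", mcmc$J)
  acc <- numeric(mcmc$J)
  fail <- 0L
  for (j in seq_len(mcmc$J)) {
    ch <- tryCatch(
      il_mh(sample, prior = c(ab$a[j], ab$b[j]), source = source,
            n_iter = mcmc$inner_n_iter, burn_in = mcmc$inner_burn_in,
            proposal_sd = psd, init = fr$theta, control = control,
            seed = (seed + j) %% .Machine$integer.max),
      error = function(e) NULL)
    if (is.null(ch)) { fail <- fail + 1L; next }
    per[[j]] <- data.frame(a = ab$a[j], b = ab$b[j],
                           theta_mean = mean(ch$draws))
    pooled[[j]] <- ch$draws
    acc[j] <- ch$acceptance_rate
  }
  if (fail > 0.1 * mcmc$J)
    stop("more than 10% of the inner chains failed", call. = FALSE)
  per <- do.call(rbind, per)
  draws <- unlist(pooled)
  th <- list(est = mean(per$theta_mean))
  q <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  out <- list(theta = th$est, se = stats::sd(draws),
              ci = c(lower = q[1], upper = q[2]),
              draws = draws, per_draw = per,
              acceptance_rate = mean(acc[acc > 0]),
              hyper = c(eps1 = hyper[[1]], eps2 = hyper[[2]], c = hyper[[3]]),
              J = mcmc$J, failures = fail, control = control, mcmc = mcmc,
              seed = seed)
  if (!is.null(t)) {
    # per-chain posterior means of the transforms, then averaged; pooled
    # draws give the E-BCI
    rf_means <- vapply(pooled[!vapply(pooled, is.null, TRUE)], function(d)
      mean(vapply(d, function(th) pinvlindley(t, th, lower.tail = FALSE),
                  numeric(1))), numeric(1))
    hf_means <- vapply(pooled[!vapply(pooled, is.null, TRUE)], function(d)
      mean(vapply(d, function(th) hinvlindley(t, th), numeric(1))),
      numeric(1))
    rf_draws <- vapply(draws, function(th)
      pinvlindley(t, th, lower.tail = FALSE), numeric(1))
    hf_draws <- vapply(draws, function(th) hinvlindley(t, th), numeric(1))
    qr <- stats::quantile(rf_draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    qh <- stats::quantile(hf_draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    out$rf <- list(est = mean(rf_means), se = stats::sd(rf_draws),
                   ci = c(lower = qr[1], upper = qr[2]))
    out$hrf <- list(est = mean(hf_means), se = stats::sd(hf_draws),
                    ci = c(lower = qh[1], upper = qh[2]))
  }
  out
}
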