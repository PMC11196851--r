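# Bayesian estimation -------------------------------------------------------
#
# theta gets a gamma(a, b) prior.  The "data source" is either the censored
# likelihood or the spacing function, giving two posteriors
#   H_LF(theta) \propto theta^{a-1} e^{-b theta} L(theta)
#   H_SF(theta) \propto theta^{a-1} e^{-b theta} P(theta)
# explored by a random-walk Metropolis-Hastings sampler under squared-error
# loss.  a = b = 0 encodes the improper noninformative limit (prior
# 1/theta); the posterior is proper as long as one failure is observed.

#' Unnormalized log-posterior of the inverse Lindley scale
#'
#' Log gamma(`a`, `b`) prior density (up to a constant) plus the censored
#' log-likelihood (`source = "lik"`) or log-spacing objective
#' (`source = "sp"`).  Returns `-Inf` for nonpositive `theta`.
#'
#' @inheritParams il_loglik
#' @param prior numeric `c(a, b)`, gamma prior shape and rate (both
#'   nonnegative; `c(0, 0)` is the noninformative limit).
#' @param source data source, `"lik"` or `"sp"`.
#' @param control spacing options for `source = "sp"`.
#' @return The unnormalized log-posterior value(s).
#' @export
il_posterior <- function(theta, sample, prior = c(a = 0, b = 0),
                         source = c("lik", "sp"),
                         control = spacing_control()) {
  source <- match.arg(source)
  sample <- .il_check_sample(sample)
  a <- prior[[1]]; b <- prior[[2]]
  if (a < 0 || b < 0) stop("prior hyperparameters must be nonnegative",
                           call. = FALSE)
  vapply(theta, function(th) {
    if (!is.finite(th) || th <= 0) return(-Inf)
    lp <- (a - 1) * log(th) - b * th
    lp + if (source == "lik") il_loglik(th, sample)
         else il_logspacing(th, sample, control = control)
  }, numeric(1))
}

#' Random-walk Metropolis--Hastings sampler for the scale parameter
#'
#' Samples the posterior of [il_posterior()] with a normal random-walk
#' proposal; nonpositive proposals are rejected outright.  The chain starts
#' at the MLE (`source = "lik"`) or MPSE (`source = "sp"`) unless `init` is
#' given, and the proposal standard deviation defaults to
#' `proposal_scale` times the Wald standard error of that starting estimate.
#'
#' @inheritParams il_posterior
#' @param n_iter,burn_in chain length and discarded initial iterations.
#' @param proposal_sd explicit proposal standard deviation (optional).
#' @param proposal_scale multiplier of the frequentist standard error used
#'   when `proposal_sd` is missing.
#' @param init optional starting value.
#' @param seed optional integer seed.
#' @return A list of class `"il_chain"`: `draws` (post burn-in),
#'   `acceptance_rate`, `burn_in`, `source`, `prior` and the starting value.
#' @examples
#' ch <- il_mh(il_fixture("rme_S1"), n_iter = 2000, burn_in = 500, seed = 1)
#' mean(ch$draws)
#' @export
il_mh <- function(sample, prior = c(a = 0, b = 0), source = c("lik", "sp"),
                  n_iter = 10000L, burn_in = 2000L, proposal_sd = NULL,
                  proposal_scale = 0.25, init = NULL,
                  control = spacing_control(), seed = NULL) {
  source <- match.arg(source)
  sample <- .il_check_sample(sample)
  stopifnot(n_iter > burn_in, burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init) || is.null(proposal_sd)) {
    fr <- .il_fit_freq(sample, if (source == "lik") "lik" else "sp",
                       control = control)
    if (is.null(init)) init <- fr$theta
    if (is.null(proposal_sd)) proposal_sd <- proposal_scale * fr$se
  }
  lp <- function(th) il_posterior(th, sample, prior, source, control)
  draws <- numeric(n_iter)
  cur <- init; lcur <- lp(cur)
  if (!is.finite(lcur)) stop("invalid starting value for the chain",
                             call. = FALSE)
  acc <- 0L
  steps <- stats::rnorm(n_iter, 0, proposal_sd)
  lu <- log(stats::runif(n_iter))
  for (i in seq_len(n_iter)) {
    cand <- cur + steps[i]
    if (cand > 0) {
      lcand <- lp(cand)
      if (lu[i] < lcand - lcur) {
        cur <- cand; lcur <- lcand; acc <- acc + 1L
      }
    }
    draws[i] <- cur
  }
  structure(list(draws = draws[(burn_in + 1L):n_iter],
                 acceptance_rate = acc / n_iter,
                 burn_in = burn_in, n_iter = n_iter, source = source,
                 prior = c(a = prior[[1]], b = prior[[2]]),
                 proposal_sd = proposal_sd, init = init),
            class = "il_chain")
}

#' @export
print.il_chain <- function(x, ...) {
  cat(sprintf(
    "Metropolis-Hastings chain (%s source): %d kept draws, %.1f%% accepted\n",
    if (x$source == "lik") "likelihood" else "spacing",
    length(x$draws), 100 * x$acceptance_rate))
  cat(sprintf("  posterior mean %0.4f, sd %0.4f\n",
              mean(x$draws), stats::sd(x$draws)))
  invisible(x)
}

# squared-error-loss summaries of a vector of theta draws for one estimand
.il_draw_summary <- function(draws, level, transform = identity) {
  v <- vapply(draws, transform, numeric(1))
  q <- stats::quantile(v, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  list(est = mean(v), se = stats::sd(v),
       ci = c(lower = q[1], upper = q[2]), draws = v)
}

.il_fit_bayes <- function(sample, method, t, level, prior, control, mcmc,
                          seed) {
  source <- if (method == "bayes_lf") "lik" else "sp"
  ch <- il_mh(sample, prior = prior, source = source,
              n_iter = mcmc$n_iter, burn_in = mcmc$burn_in,
              proposal_sd = mcmc$proposal_sd,
              proposal_scale = mcmc$proposal_scale,
              control = control, seed = seed)
  th <- .il_draw_summary(ch$draws, level)
  out <- list(theta = th$est, se = th$se, ci = th$ci,
              draws = ch$draws, acceptance_rate = ch$acceptance_rate,
              prior = c(a = prior[[1]], b = prior[[2]]),
              control = control, mcmc = mcmc)
  if (!is.null(t)) {
    rf <- .il_draw_summary(ch$draws, level, function(th)
      pinvlindley(t, th, lower.tail = FALSE))
    hf <- .il_draw_summary(ch$draws, level, function(th) hinvlindley(t, th))
    out$rf <- rf[c("est", "se", "ci")]
    out$hrf <- hf[c("est", "se", "ci")]
  }
  out
}

#' Brooks--Gelman--Rubin potential scale reduction statistic
#'
#' The classical split-free \eqn{\hat R}: with `m` chains of length `n`,
#' within-chain variance `W` and between-chain variance `B` (of the chain
#' means, times `n`), \eqn{\hat R=\sqrt{((n-1)/n\,W+B/n)/W}}.  Values near 1
#' indicate that the chains have mixed.
#'
#' @param chains a list of at least two equal-length numeric vectors (or
#'   `"il_chain"` objects).
#' @return The potential scale reduction factor (a number \eqn{\ge} roughly
#'   1).
#' @examples
#' set.seed(1)
#' gelman_rubin(list(rnorm(500), rnorm(500)))  # ~1
#' @export
gelman_rubin <- function(chains) {
  chains <- lapply(chains, function(ch)
    if (inherits(ch, "il_chain")) ch$draws else as.numeric(ch))
  m <- length(chains)
  if (m < 2L) stop("at least two chains are required", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length", call. = FALSE)
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}
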