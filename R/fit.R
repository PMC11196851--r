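# Model fitting ------------------------------------------------------------

.il_z975 <- function(level) stats::qnorm(1 - (1 - level) / 2)

# maximize an objective with analytic derivatives; golden-section bracket
# followed by Newton polishing on the score
.il_maximize <- function(obj, lower = 1e-6, upper = 1e3, init = NULL) {
  f <- function(th) obj(th)$value
  if (!is.null(init) && (init <= lower || init >= upper ||
                         !is.finite(f(init)))) init <- NULL
  grid_init <- function() {
    # coarse log-grid scan: the objective can underflow to -Inf far from
    # the optimum, which strands a blind golden-section search
    grid <- 10^seq(log10(lower), log10(upper), length.out = 121)
    fg <- vapply(grid, function(g) {
      v <- tryCatch(f(g), error = function(e) -Inf)
      if (is.finite(v)) v else -Inf
    }, numeric(1))
    i <- which.max(fg)
    if (!is.finite(fg[i]))
      stop("estimation failure: objective not finite anywhere in the bracket",
           call. = FALSE)
    stats::optimize(f, c(grid[max(i - 1L, 1L)], grid[min(i + 1L, length(grid))]),
                    maximum = TRUE, tol = 1e-10)$maximum
  }
  newton <- function(start) {
    th <- start
    for (it in 1:100) {
      d <- obj(th)
      if (!is.finite(d$score) || !is.finite(d$hessian) || d$hessian >= 0)
        return(NULL)
      cand <- th - d$score / d$hessian
      if (cand <= lower || cand >= upper) return(NULL)
      th <- cand
      if (abs(d$score) < 1e-10) break
    }
    d <- obj(th)
    if (!is.finite(d$value) || abs(d$score) > 1e-6 * max(1, abs(th)))
      return(NULL)
    list(theta = th, value = d$value, score = d$score, hessian = d$hessian)
  }
  res <- if (!is.null(init)) newton(init)
  if (is.null(res)) res <- newton(grid_init())
  if (is.null(res))
    stop("estimation failure: score did not vanish after bracket expansion",
         call. = FALSE)
  res
}

# point estimate, observed-information variance and delta-method pieces
.il_fit_freq <- function(sample, objective = c("lik", "sp"),
                         control = spacing_control(), init = NULL) {
  objective <- match.arg(objective)
  obj <- if (objective == "lik") {
    function(th) il_loglik(th, sample, deriv = TRUE)
  } else {
    function(th) il_logspacing(th, sample, control = control, deriv = TRUE)
  }
  if (is.null(init) && objective == "lik") {
    # moment-style guess: complete-sample score in theta solves a quadratic,
    # k/theta + k/(theta(1+theta)) = sum(x); a crude seed is enough here
    init <- sample$k / sum(1 / sample$times) * 2
  }
  mx <- .il_maximize(obj, init = init)
  if (mx$hessian >= 0)
    stop("degenerate information: objective is not locally concave", call. = FALSE)
  var_theta <- -1 / mx$hessian
  c(mx, list(se = sqrt(var_theta)))
}

# delta-method gradients of R(t) and h(t) in theta
.il_delta_grad <- function(theta, t) {
  x <- 1 / t
  rp <- .il_R_parts(x, theta)
  dlogf <- 2 / theta - 1 / (1 + theta) - x
  h <- dinvlindley(t, theta) / rp$R
  list(R = rp$R, dR = rp$dR, h = h, dh = h * (dlogf - rp$dR / rp$R))
}

#' MCMC settings for the Bayes and E-Bayes estimators
#'
#' @param n_iter total Metropolis--Hastings iterations per chain.
#' @param burn_in iterations discarded from the start of each chain.
#' @param proposal_scale the random-walk normal proposal standard deviation
#'   is `proposal_scale` times the Wald standard error of the initializing
#'   frequentist estimate (small values give the high acceptance rates this
#'   sampler is tuned for).
#' @param proposal_sd optional explicit proposal standard deviation,
#'   overriding `proposal_scale`.
#' @param J number of hyperprior draws for the E-Bayes estimators.
#' @param inner_n_iter,inner_burn_in per-hyperprior-draw chain sizes used by
#'   the E-Bayes estimators.
#' @return A list of class `"il_mcmc_control"`.
#' @export
mcmc_control <- function(n_iter = 10000L, burn_in = 2000L,
                         proposal_scale = 0.25, proposal_sd = NULL,
                         J = 100L, inner_n_iter = 2000L,
                         inner_burn_in = 500L) {
  stopifnot(n_iter > burn_in, burn_in >= 0, J >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 proposal_scale = proposal_scale, proposal_sd = proposal_sd,
                 J = as.integer(J), inner_n_iter = as.integer(inner_n_iter),
                 inner_burn_in = as.integer(inner_burn_in)),
            class = "il_mcmc_control")
}

#' Fit the inverse Lindley model to censored lifetime data
#'
#' Estimates the inverse Lindley scale parameter \eqn{\theta} -- and, when a
#' mission time `t` is given, the reliability \eqn{R(t)} and hazard
#' \eqn{h(t)} -- from an adaptive Type-I progressively censored sample, by
#' one of six methods:
#'
#' * `"mle"` -- maximum likelihood, with Wald interval for \eqn{\theta} and
#'   delta-method intervals for \eqn{R(t)} and \eqn{h(t)} from the observed
#'   information;
#' * `"mps"` -- maximum product of spacings, with the analogous intervals
#'   from the spacing information;
#' * `"bayes_lf"`, `"bayes_sf"` -- posterior mean under squared-error loss
#'   with a gamma(`a`, `b`) prior, using the likelihood (LF) or the spacing
#'   function (SF) as the data source, sampled by random-walk
#'   Metropolis--Hastings started at the MLE (LF) or MPSE (SF); intervals
#'   are equal-tailed credible intervals;
#' * `"ebayes_lf"`, `"ebayes_sf"` -- E-Bayesian estimates: the Bayes
#'   estimator averaged over a beta(`eps1`, `eps2`) \eqn{\times}
#'   uniform(0, `c`) hyperprior on (`a`, `b`), evaluated by Monte Carlo with
#'   `J` hyperprior draws and one Metropolis--Hastings chain per draw;
#'   intervals are equal-tailed quantiles of the draws pooled across chains.
#'
#' `prior = c(a = 0, b = 0)` is accepted as the improper noninformative
#' limit; the posterior stays proper because at least one failure is
#' observed.
#'
#' @param sample an [atipc()] sample or a numeric vector of complete
#'   failure times.
#' @param method estimation method, see Details.
#' @param t optional mission time at which reliability and hazard are
#'   estimated.
#' @param level confidence/credibility level of the reported intervals.
#' @param prior gamma prior shape `a` and rate `b` (Bayes methods).
#' @param hyper hyperprior parameters `eps1`, `eps2` (beta shapes for `a`)
#'   and `c` (uniform upper bound for `b`) for the E-Bayes methods.
#' @param control spacing options ([spacing_control()]) for the
#'   spacing-based methods.
#' @param mcmc MCMC settings ([mcmc_control()]).
#' @param init optional starting value for the frequentist optimizers.
#' @param seed optional integer seed for the MCMC-based methods.
#'
#' @return An object of class `"il_fit"` with components `theta`, `se`,
#'   `ci`, and (when `t` is supplied) `rf` and `hrf` lists holding `est`,
#'   `se` and `ci`; Bayes fits additionally carry the post-burn-in chain in
#'   `draws` and its `acceptance_rate`, and E-Bayes fits the per-hyperprior
#'   draw summaries in `per_draw` and the pooled draws.  Standard methods
#'   (`print`, `summary`, `coef`, `vcov`, `confint`, `logLik`, `predict`,
#'   `simulate`, `residuals`, `plot`) are available.
#'
#' @examples
#' fit <- il_fit(il_fixture("rme_S1"), method = "mle", t = 0.5)
#' fit                      # theta-hat 1.1756, se 0.1855
#' confint(fit)
#' predict(fit, t = c(0.5, 1, 2))
#' @export
il_fit <- function(sample,
                   method = c("mle", "mps", "bayes_lf", "bayes_sf",
                              "ebayes_lf", "ebayes_sf"),
                   t = NULL, level = 0.95,
                   prior = c(a = 0, b = 0),
                   hyper = c(eps1 = 0.75, eps2 = 0.75, c = 1),
                   control = spacing_control(),
                   mcmc = mcmc_control(),
                   init = NULL, seed = NULL) {
  method <- match.arg(method)
  sample <- .il_check_sample(sample)
  stopifnot(level > 0, level < 1)
  if (!is.null(t)) stopifnot(is.numeric(t), length(t) == 1L, t > 0)
  out <- switch(
    method,
    mle = , mps = .il_fit_point(sample, method, t, level, control, init),
    bayes_lf = , bayes_sf =
      .il_fit_bayes(sample, method, t, level, prior, control, mcmc, seed),
    ebayes_lf = , ebayes_sf =
      .il_fit_ebayes(sample, method, t, level, hyper, control, mcmc, seed))
  out$sample <- sample
  out$t <- t
  out$level <- level
  out$method <- method
  class(out) <- "il_fit"
  out
}

.il_fit_point <- function(sample, method, t, level, control, init) {
  fr <- .il_fit_freq(sample, if (method == "mle") "lik" else "sp",
                     control = control, init = init)
  zq <- .il_z975(level)
  out <- list(theta = fr$theta, se = fr$se,
              ci = c(lower = fr$theta - zq * fr$se,
                     upper = fr$theta + zq * fr$se),
              objective = fr$value, control = control)
  if (!is.null(t)) {
    g <- .il_delta_grad(fr$theta, t)
    se_R <- abs(g$dR) * fr$se
    se_h <- abs(g$dh) * fr$se
    out$rf <- list(est = g$R, se = se_R,
                   ci = c(lower = g$R - zq * se_R, upper = g$R + zq * se_R))
    out$hrf <- list(est = g$h, se = se_h,
                    ci = c(lower = g$h - zq * se_h, upper = g$h + zq * se_h))
  }
  out
}

# Methods -------------------------------------------------------------------

.il_method_label <- function(m) {
  c(mle = "Maximum likelihood", mps = "Maximum product of spacings",
    bayes_lf = "Bayes (likelihood)", bayes_sf = "Bayes (spacing function)",
    ebayes_lf = "E-Bayes (likelihood)",
    ebayes_sf = "E-Bayes (spacing function)")[[m]]
}

#' @export
print.il_fit <- function(x, digits = 4, ...) {
  cat(.il_method_label(x$method), "fit of the inverse Lindley model\n")
  cat(sprintf("  theta: %s (se %s), %g%% interval (%s, %s)\n",
              format(round(x$theta, digits)), format(round(x$se, digits)),
              100 * x$level,
              format(round(x$ci[1], digits)), format(round(x$ci[2], digits))))
  if (!is.null(x$rf)) {
    cat(sprintf("  R(%g):  %s (se %s), interval (%s, %s)\n", x$t,
                format(round(x$rf$est, digits)), format(round(x$rf$se, digits)),
                format(round(x$rf$ci[1], digits)),
                format(round(x$rf$ci[2], digits))))
    cat(sprintf("  h(%g):  %s (se %s), interval (%s, %s)\n", x$t,
                format(round(x$hrf$est, digits)),
                format(round(x$hrf$se, digits)),
                format(round(x$hrf$ci[1], digits)),
                format(round(x$hrf$ci[2], digits))))
  }
  invisible(x)
}

#' @export
summary.il_fit <- function(object, ...) {
  est <- data.frame(
    parameter = "theta", estimate = object$theta, se = object$se,
    lower = object$ci[1], upper = object$ci[2], row.names = NULL)
  if (!is.null(object$rf)) {
    est <- rbind(est, data.frame(
      parameter = c(sprintf("R(%g)", object$t), sprintf("h(%g)", object$t)),
      estimate = c(object$rf$est, object$hrf$est),
      se = c(object$rf$se, object$hrf$se),
      lower = c(object$rf$ci[1], object$hrf$ci[1]),
      upper = c(object$rf$ci[2], object$hrf$ci[2]), row.names = NULL))
  }
  structure(list(method = object$method, table = est, sample = object$sample,
                 level = object$level,
                 acceptance_rate = object$acceptance_rate),
            class = "summary.il_fit")
}

#' @export
print.summary.il_fit <- function(x, digits = 4, ...) {
  cat(.il_method_label(x$method), "fit of the inverse Lindley model\n")
  cat(sprintf("  data: k = %d failures out of n = %d (S* = %d, tau = %s)\n",
              x$sample$k, x$sample$n, x$sample$S_star, format(x$sample$tau)))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits = digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$acceptance_rate))
    cat(sprintf("  M-H acceptance rate: %.1f%%\n", 100 * x$acceptance_rate))
  invisible(x)
}

#' @export
coef.il_fit <- function(object, ...) c(theta = object$theta)

#' @export
vcov.il_fit <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("theta", "theta"))
}

#' @export
confint.il_fit <- function(object, parm = "theta", level = NULL, ...) {
  if (is.null(level) || level == object$level) {
    ci <- switch(parm, theta = object$ci,
                 rf = object$rf$ci, hrf = object$hrf$ci)
    if (is.null(ci)) stop("no interval stored for '", parm, "'")
    return(matrix(ci, 1, 2,
                  dimnames = list(parm, c("lower", "upper"))))
  }
  zq <- .il_z975(level)
  if (!is.null(object$draws)) {
    dr <- switch(parm, theta = object$draws,
                 rf = pinvlindley(object$t, 1, lower.tail = FALSE))
    if (parm == "rf") dr <- vapply(object$draws, function(th)
      pinvlindley(object$t, th, lower.tail = FALSE), numeric(1))
    if (parm == "hrf") dr <- vapply(object$draws, function(th)
      hinvlindley(object$t, th), numeric(1))
    q <- stats::quantile(dr, c((1 - level) / 2, 1 - (1 - level) / 2))
    return(matrix(q, 1, 2, dimnames = list(parm, c("lower", "upper"))))
  }
  est <- switch(parm, theta = object$theta, rf = object$rf$est,
                hrf = object$hrf$est)
  se <- switch(parm, theta = object$se, rf = object$rf$se, hrf = object$hrf$se)
  matrix(c(est - zq * se, est + zq * se), 1, 2,
         dimnames = list(parm, c("lower", "upper")))
}

#' @export
logLik.il_fit <- function(object, ...) {
  structure(il_loglik(object$theta, object$sample),
            df = 1L, nobs = object$sample$k, class = "logLik")
}

#' Reliability and hazard predictions from a fitted model
#'
#' For frequentist fits, plug-in values at the point estimate; for Bayes and
#' E-Bayes fits, posterior means of the transformed draws (the squared-error
#' loss estimate of each curve point).
#'
#' @param object an [il_fit()] object.
#' @param t vector of mission times.
#' @param ... unused.
#' @return A data frame with columns `time`, `reliability`, `hazard`.
#' @export
predict.il_fit <- function(object, t, ...) {
  stopifnot(is.numeric(t), all(t > 0))
  if (!is.null(object$draws)) {
    rel <- vapply(t, function(tt) mean(vapply(object$draws, function(th)
      pinvlindley(tt, th, lower.tail = FALSE), numeric(1))), numeric(1))
    haz <- vapply(t, function(tt) mean(vapply(object$draws, function(th)
      hinvlindley(tt, th), numeric(1))), numeric(1))
  } else {
    rel <- vapply(t, pinvlindley, numeric(1), theta = object$theta,
                  lower.tail = FALSE)
    haz <- vapply(t, hinvlindley, numeric(1), theta = object$theta)
  }
  data.frame(time = t, reliability = rel, hazard = haz)
}

#' @export
simulate.il_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- object$sample
  replicate(nsim, ratipc(n = s$n, m = s$m, scheme = s$scheme, tau = s$tau,
                         theta = object$theta), simplify = FALSE)
}

#' @export
residuals.il_fit <- function(object, ...) {
  # Cox-Snell residuals of the observed failures; unit-exponential if the
  # model holds (censoring-weighted diagnostics are out of scope)
  -pinvlindley(object$sample$times, object$theta, lower.tail = FALSE,
               log.p = TRUE)
}

#' @export
plot.il_fit <- function(x, ...) {
  if (!is.null(x$draws)) {
    op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(x$draws, type = "l", xlab = "iteration", ylab = "theta",
                   main = "trace")
    stats::acf(x$draws, main = "ACF")
    graphics::plot(stats::density(x$draws), main = "posterior", xlab = "theta")
    graphics::abline(v = x$theta, lty = 2)
  } else {
    obj <- if (x$method == "mle") {
      function(th) il_loglik(th, x$sample)
    } else {
      function(th) il_logspacing(th, x$sample, control = x$control)
    }
    grid <- seq(max(x$theta - 4 * x$se, 1e-3), x$theta + 4 * x$se,
                length.out = 200)
    graphics::plot(grid, vapply(grid, obj, numeric(1)), type = "l",
                   xlab = "theta",
                   ylab = if (x$method == "mle") "log-likelihood"
                          else "log-spacing objective",
                   main = .il_method_label(x$method))
    graphics::abline(v = x$theta, lty = 2)
  }
  invisible(x)
}
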