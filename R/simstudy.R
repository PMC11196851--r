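# Monte-Carlo evaluation harness ---------------------------------------------

#' Monte-Carlo accuracy metrics
#'
#' Average estimate, root mean squared error, mean absolute bias and (when
#' interval widths are supplied) average interval length, each with the
#' replicate count as denominator:
#' \deqn{\mathrm{Av.E}=\frac1N\sum\hat\theta_j,\quad
#'   \mathrm{RMSE}=\sqrt{\frac1N\sum(\hat\theta_j-\theta)^2},\quad
#'   \mathrm{MAB}=\frac1N\sum|\hat\theta_j-\theta|,\quad
#'   \mathrm{ACL}=\frac1N\sum(U_j-L_j).}
#'
#' @param estimates vector of point estimates over replicates.
#' @param true true value of the estimand.
#' @param widths optional vector of interval widths over replicates.
#' @return Named numeric vector `AvE`, `RMSE`, `MAB`, `ACL` (`ACL` is `NA`
#'   without widths) plus `mc_se`, the Monte-Carlo standard error of `AvE`.
#' @examples
#' il_metrics(rep(0.5, 10), true = 0.5)  # zero error by construction
#' @export
il_metrics <- function(estimates, true, widths = NULL) {
  N <- length(estimates)
  c(AvE = mean(estimates),
    RMSE = sqrt(mean((estimates - true)^2)),
    MAB = mean(abs(estimates - true)),
    ACL = if (is.null(widths)) NA_real_ else mean(widths),
    mc_se = stats::sd(estimates) / sqrt(N))
}

#' Monte-Carlo evaluation of the estimators under a censoring design
#'
#' Repeatedly simulates adaptive Type-I progressively censored inverse
#' Lindley samples under one design, fits the requested estimators on each
#' replicate, and reports the accuracy metrics of [il_metrics()] (plus
#' empirical interval coverage) for the scale parameter and, when a mission
#' time `t` is given, for the reliability and hazard at `t`.
#'
#' Each replicate uses a child seed derived deterministically from
#' `(seed, replicate)`, so results do not depend on execution order.
#' Degenerate replicates (no failure before `tau`) are redrawn and counted;
#' replicates on which an estimator fails are dropped for that estimator,
#' and more than 5\% failures abort the run.
#'
#' @inheritParams ratipc
#' @param t optional mission time for reliability/hazard metrics.
#' @param reps number of Monte-Carlo replicates.
#' @param methods subset of the [il_fit()] methods to evaluate.
#' @param level interval level used for `ACL` and coverage.
#' @param seed master integer seed.
#' @param condition_on_k if `TRUE`, redraw each replicate until the realized
#'   number of failures equals `m` (conditioning on the design's effective
#'   sample size); the default keeps every nondegenerate sample.
#' @param prior,hyper,control,mcmc passed to [il_fit()] for the Bayesian
#'   methods.
#' @return A data frame with one row per method and estimand: columns
#'   `method`, `estimand`, `true`, `AvE`, `RMSE`, `MAB`, `ACL`, `coverage`,
#'   `reps`, `failures`, `mc_se`, plus the design columns `n`, `m`, `tau`
#'   and the mean realized number of failures `mean_k`.
#' @examples
#' il_simstudy(n = 40, m = 20, scheme = rep(5, 4), tau = 0.5, theta = 0.5,
#'             reps = 25, methods = "mle", seed = 1)
#' @export
il_simstudy <- function(n, m, scheme = NULL, tau, theta, t = NULL,
                        reps = 1000L, methods = "mle", level = 0.95,
                        seed = 1L, condition_on_k = FALSE,
                        prior = c(a = 0, b = 0),
                        hyper = c(eps1 = 0.75, eps2 = 0.75, c = 1),
                        control = spacing_control(),
                        mcmc = mcmc_control(n_iter = 3000L, burn_in = 1000L,
                                            J = 25L),
                        ...) {
  methods <- match.arg(methods, c("mle", "mps", "bayes_lf", "bayes_sf",
                                  "ebayes_lf", "ebayes_sf"),
                       several.ok = TRUE)
  est <- array(NA_real_, dim = c(reps, length(methods), 3),
               dimnames = list(NULL, methods, c("theta", "rf", "hrf")))
  wid <- est; cov <- est
  ks <- integer(reps); redraws <- 0L
  true <- c(theta = theta,
            rf = if (!is.null(t)) pinvlindley(t, theta, lower.tail = FALSE)
                 else NA_real_,
            hrf = if (!is.null(t)) hinvlindley(t, theta) else NA_real_)
  for (r in seq_len(reps)) {
    child <- (as.numeric(seed) * 10007 + r) %% 2147483647
    set.seed(child)
    repeat {
      s <- ratipc(n = n, m = m, scheme = scheme, tau = tau, theta = theta)
      if (s$k == 0L) { redraws <- redraws + 1L; next }
      if (condition_on_k && s$k != m) { redraws <- redraws + 1L; next }
      break
    }
    ks[r] <- s$k
    for (mi in seq_along(methods)) {
      fit <- tryCatch(
        il_fit(s, method = methods[mi], t = t, level = level, prior = prior,
               hyper = hyper, control = control, mcmc = mcmc,
               seed = child + mi),
        error = function(e) NULL)
      if (is.null(fit)) next
      est[r, mi, "theta"] <- fit$theta
      wid[r, mi, "theta"] <- unname(diff(fit$ci))
      cov[r, mi, "theta"] <- fit$ci[1] <= theta && theta <= fit$ci[2]
      if (!is.null(t)) {
        est[r, mi, "rf"] <- fit$rf$est
        wid[r, mi, "rf"] <- unname(diff(fit$rf$ci))
        cov[r, mi, "rf"] <- fit$rf$ci[1] <= true["rf"] &&
          true["rf"] <= fit$rf$ci[2]
        est[r, mi, "hrf"] <- fit$hrf$est
        wid[r, mi, "hrf"] <- unname(diff(fit$hrf$ci))
        cov[r, mi, "hrf"] <- fit$hrf$ci[1] <= true["hrf"] &&
          true["hrf"] <= fit$hrf$ci[2]
      }
    }
  }
  estimands <- if (is.null(t)) "theta" else c("theta", "rf", "hrf")
  rows <- list()
  for (mi in seq_along(methods)) {
    nfail <- sum(is.na(est[, mi, "theta"]))
    if (nfail > 0.05 * reps)
      stop("more than 5% of replicates failed for method '", methods[mi],
           "'", call. = FALSE)
    for (e in estimands) {
      ok <- !is.na(est[, mi, e])
      met <- il_metrics(est[ok, mi, e], true[[e]], wid[ok, mi, e])
      rows[[length(rows) + 1L]] <- data.frame(
        method = methods[mi], estimand = e, true = unname(true[[e]]),
        AvE = unname(met["AvE"]), RMSE = unname(met["RMSE"]),
        MAB = unname(met["MAB"]), ACL = unname(met["ACL"]),
        coverage = mean(cov[ok, mi, e]),
        reps = sum(ok), failures = nfail, mc_se = unname(met["mc_se"]),
        n = n, m = m, tau = tau, mean_k = mean(ks), redraws = redraws)
    }
  }
  do.call(rbind, rows)
}
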