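# Gamma-prior elicitation from pilot samples ---------------------------------

#' Elicit gamma prior hyperparameters from simulated pilot samples
#'
#' Simulates `G` complete inverse Lindley samples of size `n` at a working
#' value of the scale parameter, estimates the scale on each (by maximum
#' likelihood or maximum product of spacings), and moment-matches the gamma
#' prior to the resulting estimates:
#' \deqn{\breve a = \bar\theta^2 / s^2, \qquad \breve b = \bar\theta / s^2,}
#' where \eqn{\bar\theta} and \eqn{s^2} are the sample mean and
#' (\eqn{G-1})-denominator variance of the estimates.  The gamma
#' \eqn{(\breve a, \breve b)} prior then has exactly that mean and variance,
#' and \eqn{\breve a/\breve b} equals the mean of the estimates.
#'
#' @param theta working (true) value of the scale parameter.
#' @param n size of each pilot sample (`n >= 2`).
#' @param G number of pilot samples (`G >= 2`).
#' @param estimator `"mle"` or `"mps"`.
#' @param seed optional integer seed.
#' @return A list of class `"il_elicit"` with `a`, `b`, the estimate `mean`
#'   and `var`, `G`, `n` and the `estimator` used.
#' @examples
#' il_elicit(theta = 0.5, n = 50, G = 100, seed = 1)
#' @export
il_elicit <- function(theta, n, G, estimator = c("mle", "mps"), seed = NULL) {
  estimator <- match.arg(estimator)
  .il_check_theta(theta)
  stopifnot(G >= 2, n >= 2)
  if (!is.null(seed)) set.seed(seed)
  est <- vapply(seq_len(G), function(g) {
    s <- as_atipc(rinvlindley(n, theta))
    .il_fit_freq(s, if (estimator == "mle") "lik" else "sp")$theta
  }, numeric(1))
  mm <- .il_gamma_match(est)
  structure(c(mm, list(G = G, n = n, estimator = estimator)),
            class = "il_elicit")
}

# moment-match a gamma(a, b) to a vector of estimates: a = mean^2/var,
# b = mean/var with the (G-1)-denominator variance
.il_gamma_match <- function(est) {
  m <- mean(est); v <- stats::var(est)
  if (!is.finite(v) || v <= 0)
    stop("degenerate elicitation: zero variance of the estimates",
         call. = FALSE)
  list(a = m^2 / v, b = m / v, mean = m, var = v)
}

#' @export
print.il_elicit <- function(x, ...) {
  cat(sprintf(
    "Elicited gamma prior from %d pilot %s fits (n = %d):\n", x$G,
    toupper(x$estimator), x$n))
  cat(sprintf("  a = %0.4f, b = %0.4f (prior mean %0.4f, sd %0.4f)\n",
              x$a, x$b, x$a / x$b, sqrt(x$a) / x$b))
  invisible(x)
}
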