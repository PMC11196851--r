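# Goodness of fit and model selection ----------------------------------------

#' Kolmogorov--Smirnov test of the fitted inverse Lindley model
#'
#' Computes the Kolmogorov--Smirnov distance between the empirical
#' distribution of a complete sample and the inverse Lindley distribution
#' with the supplied (typically fitted) scale, with the p-value from the
#' asymptotic Kolmogorov series
#' \eqn{2\sum_{j\ge1}(-1)^{j-1}e^{-2j^2 n D^2}}.
#'
#' @param x numeric vector of (uncensored) observations.
#' @param theta inverse Lindley scale parameter at which the fit is tested.
#' @return A list of class `"htest"` with `statistic` and `p.value`.
#' @examples
#' il_ks_test(il_fixture("rme_full")$times, theta = 1.1604)  # D = 0.1412
#' @export
il_ks_test <- function(x, theta) {
  .il_check_theta(theta)
  if (length(x) < 1L) stop("empty data", call. = FALSE)
  z <- sort(as.numeric(x))
  n <- length(z)
  Fz <- pinvlindley(z, theta)
  D <- max(pmax(seq_len(n) / n - Fz, Fz - (seq_len(n) - 1) / n))
  j <- seq_len(100)
  p <- min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * n * D^2))))
  structure(list(statistic = c(D = D), p.value = p,
                 method = "Kolmogorov-Smirnov test against the inverse Lindley distribution",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' Information criteria from a maximized log-likelihood
#'
#' Akaike (`A`), Bayesian (`B`), consistent Akaike (`CA`) and Hannan--Quinn
#' (`HQ`) criteria:
#' \deqn{A=-2\ell+2p,\quad B=-2\ell+p\log n,\quad
#'   CA=A+\frac{2p(p+1)}{n-p-1},\quad HQ=-2\ell+2p\log\log n.}
#'
#' @param loglik maximized log-likelihood.
#' @param p number of estimated parameters.
#' @param n sample size (`n > p + 1`).
#' @return Named numeric vector with elements `A`, `B`, `CA`, `HQ`.
#' @examples
#' il_ic(-46.933, p = 1, n = 30)  # A = 95.866 ... HQ = 96.314
#' @export
il_ic <- function(loglik, p = 1, n) {
  if (n <= p + 1) stop("consistent AIC undefined for n <= p + 1", call. = FALSE)
  A <- -2 * loglik + 2 * p
  c(A = A,
    B = -2 * loglik + p * log(n),
    CA = A + 2 * p * (p + 1) / (n - p - 1),
    HQ = -2 * loglik + 2 * p * log(log(n)))
}
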