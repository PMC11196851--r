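# Inverse Lindley distribution -------------------------------------------
#
# If X follows a Lindley(theta) law, Z = 1/X follows the inverse Lindley
# (IL) law with the same scale theta.  Writing tb = theta/(1+theta):
#   f(z) = theta * tb * exp(-theta/z) * (1+z) / z^3
#   F(z) = (1 + tb/z) * exp(-theta/z)
# The hazard f/(1-F) is upside-down bathtub shaped; moments do not all
# exist, which is why the procedures in this package work with the
# reliability R(t) = 1 - F(t) and hazard h(t) directly.

.il_tbar <- function(theta) theta / (1 + theta)

.il_check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("'theta' must be a single positive number", call. = FALSE)
  invisible(theta)
}

# log F(z) evaluated stably; z <= 0 maps to -Inf (F = 0 by convention)
.il_logcdf <- function(z, theta) {
  out <- rep(-Inf, length(z))
  ok <- is.finite(z) & z > 0
  x <- 1 / z[ok]
  out[ok] <- log1p(.il_tbar(theta) * x) - theta * x
  out[is.infinite(z) & z > 0] <- 0
  out
}

#' The inverse Lindley distribution
#'
#' Density, distribution function, quantile function, random generation and
#' hazard rate for the inverse Lindley distribution with scale parameter
#' `theta`.
#'
#' The density is
#' \deqn{f(z;\theta)=\frac{\theta^2}{1+\theta}\,
#'   e^{-\theta/z}\,\frac{1+z}{z^3},\qquad z>0,}
#' with distribution function
#' \eqn{F(z;\theta)=(1+\bar\theta/z)e^{-\theta/z}} where
#' \eqn{\bar\theta=\theta/(1+\theta)}.  The hazard rate
#' \eqn{h(z)=f(z)/(1-F(z))} is unimodal (upside-down bathtub).
#'
#' `F` has no elementary inverse; `qinvlindley()` solves \eqn{F(z)=p} by a
#' safeguarded root search on the monotone function
#' \eqn{x\mapsto(1+\bar\theta x)e^{-\theta x}}, \eqn{x=1/z}, followed by
#' Newton polishing, so that the round-trip `pinvlindley(qinvlindley(p))`
#' holds to near machine precision.
#'
#' @param x,q,t vector of positive quantiles (times).
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param theta positive scale parameter.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   \eqn{P(Z \le z)}, otherwise the reliability \eqn{P(Z > z)}.
#'
#' @return `dinvlindley` the density, `pinvlindley` the distribution function
#'   (or reliability with `lower.tail = FALSE`), `qinvlindley` the quantile
#'   function, `rinvlindley` random deviates and `hinvlindley` the hazard
#'   rate, each a numeric vector.
#'
#' @examples
#' pinvlindley(0.1, theta = 0.5, lower.tail = FALSE)  # reliability, 0.9708
#' hinvlindley(0.1, theta = 0.5)                      # hazard, 1.2724
#' qinvlindley(0.5, theta = 0.5)                      # median
#' @name invlindley
NULL

#' @rdname invlindley
#' @export
dinvlindley <- function(x, theta, log = FALSE) {
  .il_check_theta(theta)
  out <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  z <- x[ok]
  out[ok] <- 2 * log(theta) - log1p(theta) - theta / z + log1p(z) - 3 * log(z)
  if (log) out else exp(out)
}

#' @rdname invlindley
#' @export
pinvlindley <- function(q, theta, lower.tail = TRUE, log.p = FALSE) {
  .il_check_theta(theta)
  lF <- .il_logcdf(q, theta)
  if (lower.tail) {
    if (log.p) lF else exp(lF)
  } else {
    # 1 - F computed as -expm1(log F) to keep accuracy when F is near 1
    r <- -expm1(lF)
    if (log.p) log(r) else r
  }
}

#' @rdname invlindley
#' @export
qinvlindley <- function(p, theta, lower.tail = TRUE, log.p = FALSE) {
  .il_check_theta(theta)
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  tb <- .il_tbar(theta)
  G <- function(x) (1 + tb * x) * exp(-theta * x)   # = F(1/x), decreasing in x
  vapply(p, function(pp) {
    hi <- 1
    while (G(hi) > pp && hi < 1e12) hi <- hi * 4
    x <- stats::uniroot(function(x) G(x) - pp, c(0, hi),
                        tol = .Machine$double.eps^0.75)$root
    # Newton polish; G'(x) = -Lindley density of X = 1/Z
    for (it in 1:3) {
      gx <- -theta^2 / (1 + theta) * (1 + x) * exp(-theta * x)
      step <- (G(x) - pp) / gx
      if (!is.finite(step)) break
      x <- max(x - step, .Machine$double.xmin)
    }
    1 / x
  }, numeric(1))
}

#' @rdname invlindley
#' @export
rinvlindley <- function(n, theta) {
  .il_check_theta(theta)
  qinvlindley(stats::runif(n), theta)
}

#' @rdname invlindley
#' @export
hinvlindley <- function(t, theta) {
  .il_check_theta(theta)
  dinvlindley(t, theta) / pinvlindley(t, theta, lower.tail = FALSE)
}
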