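# Log-likelihood and log-spacing objectives with analytic derivatives -----
#
# Both objectives share the censoring terms S_i * log R(z_i) + S* log R(tau).
# Writing x = 1/z and tb = theta/(1+theta), the reliability is
#   R = 1 - (1 + tb*x) * exp(-theta*x),
# with derivatives in theta
#   dR/dtheta  = x e^{-theta x} (1 + tb x - tb'),         tb'  = 1/(1+theta)^2
#   d2R/dtheta2 = x e^{-theta x} (tb' x - tb'' - x (1 + tb x - tb')),
#                                                          tb'' = -2/(1+theta)^3
# so that d log R = (dR)/R and d2 log R = (d2R)/R - ((dR)/R)^2.

# reliability and its first two theta-derivatives at x = 1/z
.il_R_parts <- function(x, theta) {
  tb <- theta / (1 + theta)
  tb1 <- 1 / (1 + theta)^2
  tb2 <- -2 / (1 + theta)^3
  e <- exp(-theta * x)
  Fv <- (1 + tb * x) * e
  R <- -expm1(log1p(tb * x) - theta * x)
  dR <- x * e * (1 + tb * x - tb1)
  d2R <- x * e * (tb1 * x - tb2 - x * (1 + tb * x - tb1))
  list(F = Fv, R = R, dR = dR, d2R = d2R)
}

.il_check_sample <- function(sample) {
  sample <- as_atipc(sample)
  if (sample$k < 1L)
    stop("degenerate sample with no observed failures cannot be fitted",
         call. = FALSE)
  sample
}

#' Censored log-likelihood of the inverse Lindley model
#'
#' Evaluates the full log-likelihood of an adaptive Type-I progressively
#' censored inverse Lindley sample,
#' \deqn{\ell(\theta)=\sum_{i=1}^k \log f(z_i;\theta)
#'   +\sum_{i=1}^k S_i\log R(z_i;\theta)+S^*\log R(\tau;\theta),}
#' including the \eqn{\theta}-free density constants, so that
#' \eqn{-2\ell} plugs directly into information criteria.  For a complete
#' sample it reduces to the sum of log densities.
#'
#' @param theta positive scale parameter (vectorized).
#' @param sample an [atipc()] sample, or a numeric vector of complete
#'   failure times.
#' @param deriv if `TRUE`, return a list with elements `value`, `score` and
#'   `hessian` (analytic first and second derivatives in `theta`).
#' @return The log-likelihood value(s), or a list when `deriv = TRUE`.
#' @examples
#' il_loglik(1.1604, il_fixture("rme_full"))
#' @export
il_loglik <- function(theta, sample, deriv = FALSE) {
  sample <- .il_check_sample(sample)
  if (length(theta) > 1L && !deriv)
    return(vapply(theta, il_loglik, numeric(1), sample = sample))
  .il_check_theta(theta)
  z <- sample$times; x <- 1 / z; k <- sample$k
  S <- sample$S_applied; Sst <- sample$S_star
  cen_x <- c(x[S > 0], if (Sst > 0) 1 / sample$tau)
  cen_w <- c(S[S > 0], if (Sst > 0) Sst)
  ll <- 2 * k * log(theta) - k * log1p(theta) - theta * sum(x) +
    sum(log1p(z) - 3 * log(z))
  if (length(cen_w)) {
    rp <- .il_R_parts(cen_x, theta)
    ll <- ll + sum(cen_w * log(rp$R))
  }
  if (!deriv) return(ll)
  sc <- 2 * k / theta - k / (1 + theta) - sum(x)
  he <- -2 * k / theta^2 + k / (1 + theta)^2
  if (length(cen_w)) {
    dlr <- rp$dR / rp$R
    sc <- sc + sum(cen_w * dlr)
    he <- he + sum(cen_w * (rp$d2R / rp$R - dlr^2))
  }
  list(value = ll, score = sc, hessian = he)
}

#' Spacing-handling options for maximum product of spacings
#'
#' @param boundary rule for the upper (k+1)-th spacing: `"one"` (default)
#'   uses \eqn{1 - F(z_k)}; `"tau"` uses \eqn{F(\tau) - F(z_k)}.
#' @param ties treatment of zero spacings caused by tied observations:
#'   `"merge"` (default) drops them, leaving one spacing across each run of
#'   ties; `"density"` substitutes the density at the tied value
#'   (Cheng--Amin).
#' @return A list of class `"il_spacing_control"`.
#' @export
spacing_control <- function(boundary = c("one", "tau"),
                            ties = c("merge", "density")) {
  structure(list(boundary = match.arg(boundary), ties = match.arg(ties)),
            class = "il_spacing_control")
}

#' Censored log-spacing objective of the inverse Lindley model
#'
#' Evaluates the log product-of-spacings objective
#' \deqn{p(\theta)=\sum_{i=1}^{k+1}\log D_i
#'   +\sum_{i=1}^k S_i\log R(z_i;\theta)+S^*\log R(\tau;\theta),}
#' with spacings \eqn{D_i = F(z_i)-F(z_{i-1})}, \eqn{z_0=0}, and the upper
#' spacing set by the boundary rule of [spacing_control()].  Tied
#' observations would give zero spacings; they are handled by the tie rule.
#'
#' @inheritParams il_loglik
#' @param control an [spacing_control()] list.
#' @return The objective value(s), or a list with `value`, `score`,
#'   `hessian` when `deriv = TRUE`.
#' @examples
#' il_logspacing(1.1, il_fixture("rme_S1"))
#' @export
il_logspacing <- function(theta, sample, control = spacing_control(),
                          deriv = FALSE) {
  sample <- .il_check_sample(sample)
  if (length(theta) > 1L && !deriv)
    return(vapply(theta, il_logspacing, numeric(1), sample = sample,
                  control = control))
  .il_check_theta(theta)
  z <- sample$times; x <- 1 / z; k <- sample$k
  S <- sample$S_applied; Sst <- sample$S_star
  rp <- .il_R_parts(x, theta)
  Fz <- rp$F; dFz <- -rp$dR; d2Fz <- -rp$d2R
  # interior spacings D_i = F(z_i) - F(z_{i-1}); ties give D_i = 0
  tied <- c(FALSE, z[-1] == z[-k])
  if (k > 1L && all(tied[-1]))
    stop("all observations tied: spacing objective is degenerate", call. = FALSE)
  D <- diff(c(0, Fz)); dD <- diff(c(0, dFz)); d2D <- diff(c(0, d2Fz))
  if (any(tied)) {
    if (control$ties == "merge") {
      D <- D[!tied]; dD <- dD[!tied]; d2D <- d2D[!tied]
    } else {
      # substitute f(z_i; theta); log f = 2 log th - log(1+th) - th x + const
      D[tied] <- dinvlindley(z[tied], theta)
      dl <- 2 / theta - 1 / (1 + theta) - x[tied]
      d2l <- -2 / theta^2 + 1 / (1 + theta)^2
      dD[tied] <- D[tied] * dl
      d2D[tied] <- D[tied] * (d2l + dl^2)
    }
  }
  if (any(D < 0)) stop("negative spacing encountered (internal error)")
  if (control$boundary == "one") {
    rk <- .il_R_parts(x[k], theta)
    D <- c(D, rk$R); dD <- c(dD, rk$dR); d2D <- c(d2D, rk$d2R)
  } else {
    if (!is.finite(sample$tau))
      stop("boundary rule 'tau' requires a finite tau", call. = FALSE)
    rt <- .il_R_parts(1 / sample$tau, theta)
    D <- c(D, rt$F - Fz[k])                    # F(tau) - F(z_k)
    dD <- c(dD, -rt$dR - dFz[k])               # dF/dtheta = -dR/dtheta
    d2D <- c(d2D, -rt$d2R - d2Fz[k])
  }
  val <- sum(log(D))
  cen_x <- c(x[S > 0], if (Sst > 0) 1 / sample$tau)
  cen_w <- c(S[S > 0], if (Sst > 0) Sst)
  if (length(cen_w)) {
    rc <- .il_R_parts(cen_x, theta)
    val <- val + sum(cen_w * log(rc$R))
  }
  if (!deriv) return(val)
  dl <- dD / D
  sc <- sum(dl)
  he <- sum(d2D / D - dl^2)
  if (length(cen_w)) {
    dlr <- rc$dR / rc$R
    sc <- sc + sum(cen_w * dlr)
    he <- he + sum(cen_w * (rc$d2R / rc$R - dlr^2))
  }
  list(value = val, score = sc, hessian = he)
}
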