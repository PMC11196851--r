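# Independent oracles used across the test files.

# Secondary real branch W_{-1} of the Lambert W function on (-1/e, 0),
# via Newton iteration; independent of the package's quantile solver.
lambertWm1 <- function(y) {
  stopifnot(y > -exp(-1), y < 0)
  w <- log(-y) - log(-log(-y))  # asymptotic seed, w <= -1
  for (i in 1:80) {
    e <- exp(w)
    delta <- (w * e - y) / (e * (w + 1))
    w <- w - delta
    if (abs(delta) < 1e-14) break
  }
  w
}

# Closed-form inverse Lindley quantile through the Lambert-W relation:
# u e^{-u} = p (1+theta) e^{-(1+theta)}, u = 1 + theta + theta/z > 1.
qil_lambert <- function(p, theta) {
  y <- -p * (1 + theta) * exp(-(1 + theta))
  u <- -lambertWm1(y)
  theta / (u - 1 - theta)
}

# Brute-force adaptive Type-I progressive censoring: simulate all n latent
# lifetimes, then apply removals/termination by direct bookkeeping, removing
# surviving units uniformly at random.
bf_atipc <- function(n, m, scheme, tau, theta) {
  latent <- sort(rinvlindley(n, theta))
  alive <- rep(TRUE, n)
  k <- 0L; i <- 0L
  times <- numeric(0)
  repeat {
    idx <- which(alive)
    if (!length(idx)) break
    nxt <- idx[which.min(latent[idx])]
    if (latent[nxt] > tau) break
    i <- i + 1L
    times <- c(times, latent[nxt])
    alive[nxt] <- FALSE
    if (i <= m - 1L && i <= length(scheme) && scheme[i] > 0) {
      surv <- which(alive)
      rem <- min(scheme[i], length(surv))
      if (rem > 0) alive[sample(surv, rem)] <- FALSE
    }
  }
  list(k = length(times), S_star = sum(alive), times = times)
}

# Posterior mean of transform(theta) by adaptive quadrature of the
# unnormalized posterior (either data source).
quad_post_mean <- function(sample, prior = c(0, 0), source = "lik",
                           transform = identity,
                           control = spacing_control()) {
  lp <- function(th) il_posterior(th, sample, prior, source, control)
  mode <- stats::optimize(lp, c(1e-3, 50), maximum = TRUE,
                          tol = 1e-10)$maximum
  M <- lp(mode)
  # Laplace width so the integration window brackets the posterior spike
  sd <- 1 / sqrt(-fd2(lp, mode, h = mode * 1e-4))
  lo <- max(1e-8, mode - 15 * sd); hi <- mode + 15 * sd
  f0 <- function(th) exp(lp(th) - M)
  f1 <- function(th) vapply(th, transform, numeric(1)) * f0(th)
  Z <- stats::integrate(function(th) vapply(th, f0, numeric(1)), lo, hi,
                        rel.tol = 1e-10)$value
  stats::integrate(function(th) f1(th), lo, hi, rel.tol = 1e-10)$value / Z
}

# Batch-means Monte-Carlo standard error of a (possibly autocorrelated)
# chain mean.
bm_se <- function(x, nb = 40) {
  b <- floor(length(x) / nb)
  means <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * b + 1):(i * b)]),
                  numeric(1))
  stats::sd(means) / sqrt(nb)
}

# central finite differences
fd1 <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)
fd2 <- function(f, x, h = 1e-4) (f(x + h) - 2 * f(x) + f(x - h)) / h^2
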