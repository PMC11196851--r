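# Adaptive Type-I progressively censored samples --------------------------
#
# A life test starts with n units.  At the i-th observed failure,
# i = 1, ..., m-1, scheme[i] surviving units are withdrawn.  After the
# (m-1)-th failure the test keeps running and failures keep being recorded,
# but no further planned removals happen; at the fixed time tau every unit
# still on test (S*) is withdrawn and the experiment ends.  The number of
# observed failures k is therefore random and may be smaller or larger
# than m.

#' Construct an adaptively censored sample
#'
#' Builds an adaptive Type-I progressively censored (AT-IPC) sample from the
#' observed failure times and the censoring plan, deriving the removals
#' actually applied and the terminal removal count
#' \eqn{S^* = n - k - \sum_{i \le \min(k, m-1)} S_i}.
#'
#' Planned removals are applied only at the first \eqn{m-1} failures; any
#' scheme entries beyond position \eqn{m-1}, and all entries past the
#' realized number of failures \eqn{k}, are ignored.  A complete sample is
#' the degenerate case `tau = Inf` with an all-zero scheme and `m = n`.
#'
#' @param times ordered vector of observed failure times, all `<= tau`.
#' @param n total number of units put on test.
#' @param m planned number of failures (`1 <= m <= n`).
#' @param scheme planned removal counts \eqn{S_1, S_2, \ldots}; shorter
#'   vectors are padded with zeros, and a full-length vector with trailing
#'   zeros is accepted.  Defaults to no planned removals.
#' @param tau termination time of the experiment (`Inf` encodes a complete
#'   sample).
#'
#' @return An object of class `"atipc"`: a list with elements `times`, `n`,
#'   `m`, `scheme`, `S_applied` (removals applied at each observed failure),
#'   `S_star`, `tau` and `k`.
#'
#' @examples
#' # sample S1 of the repairable mechanical equipment data
#' s <- atipc(c(0.11, 0.30, 0.45, 0.59, 0.74, 0.77, 1.06, 1.17, 1.23, 1.46),
#'            n = 30, m = 15, scheme = c(rep(3, 5), rep(0, 10)), tau = 1.5)
#' s$S_star  # 5 units withdrawn at tau
#' @seealso [ratipc()] to simulate such samples, [il_fit()] to fit them.
#' @export
atipc <- function(times, n, m = n, scheme = NULL, tau = Inf) {
  times <- as.numeric(times)
  k <- length(times)
  if (k < 1L) stop("at least one observed failure is required (k >= 1)", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be sorted increasingly", call. = FALSE)
  if (any(times <= 0)) stop("failure times must be positive", call. = FALSE)
  if (!(tau > 0)) stop("'tau' must be positive", call. = FALSE)
  if (any(times > tau)) stop("all failure times must be <= tau", call. = FALSE)
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1L || m > n) stop("'m' must satisfy 1 <= m <= n", call. = FALSE)
  if (is.null(scheme)) scheme <- integer(max(m - 1L, 0L))
  scheme <- as.integer(scheme)
  if (any(scheme < 0L)) stop("removal counts must be nonnegative", call. = FALSE)
  if (m > 1L && sum(scheme[seq_len(min(length(scheme), m - 1L))]) > n - m)
    stop("infeasible plan: planned removals exceed n - m", call. = FALSE)
  S_applied <- integer(k)
  idx <- seq_len(min(k, m - 1L, length(scheme)))
  S_applied[idx] <- scheme[idx]
  S_star <- n - k - sum(S_applied)
  if (S_star < 0L)
    stop("inconsistent plan: n - k - sum(S_applied) = ", S_star, " < 0", call. = FALSE)
  structure(
    list(times = times, n = n, m = m, scheme = scheme,
         S_applied = S_applied, S_star = as.integer(S_star),
         tau = tau, k = k),
    class = "atipc")
}

#' @export
print.atipc <- function(x, ...) {
  cat("Adaptive Type-I progressively censored sample\n")
  cat(sprintf("  n = %d, m = %d, tau = %s, observed failures k = %d, S* = %d\n",
              x$n, x$m, format(x$tau), x$k, x$S_star))
  cat("  times:", paste(format(x$times, trim = TRUE), collapse = " "), "\n")
  if (any(x$S_applied > 0))
    cat("  removals applied:", paste(x$S_applied, collapse = " "), "\n")
  invisible(x)
}

#' Coerce to an AT-IPC sample
#'
#' Numeric vectors are interpreted as complete (uncensored) samples.
#'
#' @param x an `"atipc"` object or a numeric vector of failure times.
#' @return An `"atipc"` object.
#' @export
as_atipc <- function(x) {
  if (inherits(x, "atipc")) return(x)
  if (is.numeric(x)) return(atipc(sort(x), n = length(x)))
  stop("cannot coerce object of class '", class(x)[1L], "' to 'atipc'", call. = FALSE)
}

.is_complete <- function(sample) {
  sample$S_star == 0L && all(sample$S_applied == 0L)
}

#' Simulate an adaptive Type-I progressively censored sample
#'
#' Draws one AT-IPC sample from the inverse Lindley distribution by
#' sequential conditional sampling: with `r` units at risk after time `t`,
#' the next failure time is \eqn{F^{-1}(1-(1-F(t))U^{1/r})} for
#' \eqn{U\sim U(0,1)}.  Planned removals are applied after each of the first
#' \eqn{m-1} failures; generation stops at the first candidate failure
#' beyond `tau` (or when the risk set empties), and the remaining risk set
#' becomes `S_star`.
#'
#' If the scheme requests more removals than units remain at risk, only the
#' remaining units are removed (the truncation is visible in `S_applied`).
#' If the first failure falls beyond `tau` the realized sample is degenerate
#' (k = 0); the returned object then carries `attr(, "degenerate") = TRUE`
#' and cannot be fitted.
#'
#' @inheritParams atipc
#' @param theta positive inverse Lindley scale parameter.
#' @param seed optional integer seed (`set.seed()` is called when supplied).
#'
#' @return An `"atipc"` object.
#' @examples
#' s <- ratipc(n = 40, m = 20, scheme = rep(5, 4), tau = 1.5,
#'             theta = 0.5, seed = 1)
#' s$n == s$k + sum(s$S_applied) + s$S_star  # accounting identity
#' @export
ratipc <- function(n, m = n, scheme = NULL, tau = Inf, theta, seed = NULL) {
  .il_check_theta(theta)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n); m <- as.integer(m)
  if (is.null(scheme)) scheme <- integer(max(m - 1L, 0L))
  scheme <- as.integer(scheme)
  risk <- n; Fcur <- 0
  times <- numeric(0); S_applied <- integer(0)
  i <- 0L; S_star <- 0L
  while (risk > 0L) {
    u <- stats::runif(1)
    p <- 1 - (1 - Fcur) * u^(1 / risk)
    z <- qinvlindley(p, theta)
    if (z > tau) { S_star <- risk; break }
    i <- i + 1L
    times <- c(times, z)
    risk <- risk - 1L
    rem <- if (i <= m - 1L && i <= length(scheme)) min(scheme[i], risk) else 0L
    S_applied <- c(S_applied, as.integer(rem))
    risk <- risk - rem
    Fcur <- pinvlindley(z, theta)
  }
  if (length(times) == 0L) {
    out <- structure(
      list(times = numeric(0), n = n, m = m, scheme = scheme,
           S_applied = integer(0), S_star = as.integer(n),
           tau = tau, k = 0L),
      class = "atipc")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- structure(
    list(times = times, n = n, m = m, scheme = scheme,
         S_applied = S_applied, S_star = S_star,
         tau = tau, k = length(times)),
    class = "atipc")
  out
}

# File interchange ---------------------------------------------------------
# CSV with columns time,removed (one row per observed failure) plus a JSON
# sidecar <path>.json holding n, m, tau and the planned scheme.

#' Read and write AT-IPC samples
#'
#' Samples are stored as a two-column CSV (`time`, `removed`) with one row
#' per observed failure, together with a JSON sidecar `<path>.json` that
#' records `n`, `m`, `tau`, the planned scheme and `S_star`.  The pair
#' round-trips losslessly at full printed precision.
#'
#' @param sample an `"atipc"` object.
#' @param path path of the CSV file (the sidecar gets `.json` appended).
#' @return `read_atipc()` returns an `"atipc"` object; `write_atipc()`
#'   returns `path` invisibly.
#' @export
write_atipc <- function(sample, path) {
  stopifnot(inherits(sample, "atipc"))
  utils::write.csv(
    data.frame(time = format(sample$times, trim = TRUE, digits = 15),
               removed = sample$S_applied),
    path, row.names = FALSE, quote = FALSE)
  meta <- list(n = sample$n, m = sample$m,
               tau = if (is.finite(sample$tau)) sample$tau else "Inf",
               scheme = sample$scheme, S_star = sample$S_star)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_atipc
#' @export
read_atipc <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(time = "character"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tau <- meta$tau
  if (is.character(tau) || is.null(tau)) tau <- Inf
  atipc(as.numeric(tab$time), n = meta$n, m = meta$m,
        scheme = meta$scheme, tau = tau)
}
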