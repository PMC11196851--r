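# Bundled data fixtures -------------------------------------------------------
#
# Two published reliability data sets and the six adaptively censored
# sub-samples drawn from them:
#   rme_full  - 30 times between failures of repairable mechanical equipment
#   art_full  - 40 active repair times of an airborne communication
#               transceiver
# Values are stored exactly as printed.

.il_fixture_data <- local({
  rme <- c(0.11, 0.30, 0.40, 0.45, 0.59, 0.63, 0.70, 0.71, 0.74, 0.77,
           0.94, 1.06, 1.17, 1.23, 1.23, 1.24, 1.43, 1.46, 1.49, 1.74,
           1.82, 1.86, 1.97, 2.23, 2.37, 2.46, 2.63, 3.46, 4.36, 4.73)
  art <- c(0.50, 0.60, 0.60, 0.70, 0.70, 0.70, 0.80, 0.80, 1.00, 1.00,
           1.00, 1.00, 1.10, 1.30, 1.50, 1.50, 1.50, 1.50, 2.00, 2.00,
           2.20, 2.50, 2.70, 3.00, 3.00, 3.30, 4.00, 4.00, 4.50, 4.70,
           5.00, 5.40, 5.40, 7.00, 7.50, 8.80, 9.00, 10.2, 22.0, 24.50)
  list(
    rme_full = list(times = rme, n = 30L, m = 30L, scheme = NULL, tau = Inf),
    art_full = list(times = art, n = 40L, m = 40L, scheme = NULL, tau = Inf),
    rme_S1 = list(
      times = c(0.11, 0.30, 0.45, 0.59, 0.74, 0.77, 1.06, 1.17, 1.23, 1.46),
      n = 30L, m = 15L, scheme = c(rep(3L, 5), rep(0L, 10)), tau = 1.5),
    rme_S2 = list(
      times = c(0.11, 0.30, 0.40, 0.45, 0.59, 0.63, 0.71, 0.74, 0.94, 1.17,
                1.49, 1.74),
      n = 30L, m = 15L, scheme = c(rep(0L, 5), rep(3L, 5), rep(0L, 5)),
      tau = 1.8),
    rme_S3 = list(
      times = c(0.11, 0.30, 0.40, 0.45, 0.59, 0.63, 0.70, 0.71, 0.74, 0.77,
                0.94, 1.06, 1.24, 1.46, 1.74, 1.86, 1.97),
      n = 30L, m = 15L, scheme = c(rep(0L, 10), rep(3L, 5)), tau = 2.1),
    art_S1 = list(
      times = c(0.50, 0.60, 0.70, 0.80, 1.00, 1.00, 1.30, 1.50, 1.50, 2.00,
                2.70, 3.00, 3.30, 4.00, 4.70),
      n = 40L, m = 20L, scheme = c(rep(5L, 4), rep(0L, 16)), tau = 4.8),
    art_S2 = list(
      times = c(0.50, 0.60, 0.60, 0.70, 0.70, 0.70, 0.80, 0.80, 1.00, 1.00,
                1.30, 1.50, 1.50, 2.00, 2.50, 2.70, 3.30),
      n = 40L, m = 20L, scheme = c(rep(0L, 8), rep(5L, 4), rep(0L, 8)),
      tau = 3.4),
    art_S3 = list(
      times = c(0.50, 0.60, 0.60, 0.70, 0.70, 0.70, 0.80, 0.80, 1.00, 1.00,
                1.00, 1.00, 1.10, 1.30, 1.50, 1.50, 1.50, 2.00, 2.20, 2.70,
                3.00, 3.30, 4.00, 4.50),
      n = 40L, m = 20L, scheme = c(rep(0L, 16), rep(5L, 4)), tau = 4.6))
})

#' Bundled reliability data sets and censored sub-samples
#'
#' Returns one of the published fixtures as an [atipc()] object: the full
#' repairable-mechanical-equipment (`"rme_full"`, 30 failure times) or
#' airborne-transceiver active-repair (`"art_full"`, 40 times) data, or one
#' of the three adaptively censored sub-samples of each
#' (`"rme_S1"`..`"rme_S3"`, `"art_S1"`..`"art_S3"`).
#'
#' @param name fixture name.
#' @return An `"atipc"` object (complete fixtures have `tau = Inf` and no
#'   removals).
#' @examples
#' il_fixture("rme_S1")   # k = 10 failures, S* = 5
#' @export
il_fixture <- function(name) {
  if (!name %in% names(.il_fixture_data))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.il_fixture_data), collapse = ", "), call. = FALSE)
  f <- .il_fixture_data[[name]]
  atipc(f$times, n = f$n, m = f$m, scheme = f$scheme, tau = f$tau)
}
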