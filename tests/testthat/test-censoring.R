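# Construction, validation and simulation of AT-IPC samples.

test_that("terminal removal counts of all six published sub-samples are recovered", {
  expect_identical(il_fixture("rme_S1")$S_star, 5L)
  expect_identical(il_fixture("rme_S2")$S_star, 3L)
  expect_identical(il_fixture("rme_S3")$S_star, 1L)
  expect_identical(il_fixture("art_S1")$S_star, 5L)
  expect_identical(il_fixture("art_S2")$S_star, 3L)
  expect_identical(il_fixture("art_S3")$S_star, 1L)
  # removals stop at failure m-1 even when more scheme entries exist
  s3 <- il_fixture("rme_S3")   # k = 17 > m - 1 = 14
  expect_identical(sum(s3$S_applied), 12L)
  expect_true(all(s3$S_applied[15:17] == 0L))
})

test_that("complete data is the degenerate censoring case", {
  s <- atipc(sort(c(2, 1, 3)), n = 3)
  expect_identical(s$k, 3L)
  expect_identical(s$S_star, 0L)
  expect_true(all(s$S_applied == 0L))
  expect_identical(as_atipc(c(2, 1, 3))$times, c(1, 2, 3))
})

test_that("invalid samples are rejected", {
  expect_error(atipc(numeric(0), n = 5), "at least one")
  expect_error(atipc(c(1, 2), n = 10, m = 5, scheme = rep(4, 4), tau = 3),
               "infeasible")
  expect_error(atipc(1:9 / 10, n = 8, m = 8, tau = 1), "inconsistent")
  expect_error(atipc(c(1, 2), n = 5, tau = 1.5), "<= tau")
  expect_error(atipc(c(2, 1, 3), n = 3), "sorted")
})

test_that("simulated samples satisfy the accounting identity for every seed", {
  for (seed in 1:300) {
    s <- ratipc(n = 20, m = 10, scheme = c(2, 2, 2, 2, 2), tau = 1.2,
                theta = 0.5, seed = seed)
    expect_identical(s$n, s$k + sum(s$S_applied) + s$S_star)
    if (s$k > 0) expect_true(all(s$times <= s$tau))
  }
})

test_that("no censoring reduces the simulator to complete i.i.d. sampling", {
  s <- ratipc(n = 25, m = 25, tau = Inf, theta = 0.8, seed = 3)
  expect_identical(s$k, 25L)
  expect_identical(s$S_star, 0L)
  expect_false(is.unsorted(s$times))
})

test_that("generated order statistics follow the classical order-statistic law", {
  # with no removals and tau = Inf the j-th failure time has
  # F(z_(j)) ~ Beta(j, n - j + 1)
  n <- 10; reps <- 2000
  set.seed(99)
  U <- t(replicate(reps, pinvlindley(ratipc(n = n, theta = 0.5)$times, 0.5)))
  for (j in c(1L, 5L, 10L)) {
    ks <- suppressWarnings(
      stats::ks.test(U[, j], stats::pbeta, shape1 = j, shape2 = n - j + 1))
    expect_gt(ks$p.value, 1e-3)
  }
})

test_that("sequential generator agrees with the brute-force latent-lifetime oracle", {
  # small design: compare the joint (k, S*) distribution
  reps <- 3000
  set.seed(1)
  seqr <- replicate(reps, {
    s <- ratipc(n = 6, m = 3, scheme = c(1, 1), tau = 1.5, theta = 0.5)
    paste(s$k, s$S_star)
  })
  set.seed(2)
  bf <- replicate(reps, {
    s <- bf_atipc(n = 6, m = 3, scheme = c(1, 1), tau = 1.5, theta = 0.5)
    paste(s$k, s$S_star)
  })
  lev <- union(unique(seqr), unique(bf))
  p1 <- table(factor(seqr, lev)) / reps
  p2 <- table(factor(bf, lev)) / reps
  expect_lt(max(abs(p1 - p2)), 4 * sqrt(0.25 / reps) * 2)
  # larger design: mean realized k within 2 Monte-Carlo s.e.
  reps <- 2000
  set.seed(5)
  k1 <- replicate(reps, ratipc(n = 40, m = 20, scheme = rep(5, 4), tau = 1.5,
                               theta = 0.5)$k)
  set.seed(6)
  k2 <- replicate(reps, bf_atipc(n = 40, m = 20, scheme = rep(5, 4),
                                 tau = 1.5, theta = 0.5)$k)
  se <- sqrt(var(k1) / reps + var(k2) / reps)
  expect_lt(abs(mean(k1) - mean(k2)), 2 * se)
})

test_that("samples round-trip through the CSV + JSON sidecar format", {
  for (name in c("rme_S1", "art_S2", "art_full")) {
    s <- il_fixture(name)
    path <- tempfile(fileext = ".csv")
    write_atipc(s, path)
    s2 <- read_atipc(path)
    expect_identical(s2$times, s$times)
    expect_identical(s2$S_applied, s$S_applied)
    expect_identical(s2$S_star, s$S_star)
    expect_identical(s2$tau, s$tau)
    unlink(c(path, paste0(path, ".json")))
  }
})
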