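test_that("identical series produce no clusters", {
  withr::with_seed(1, {
    A <- matrix(rnorm(6 * 40), 6)
  })
  expect_warning(ct <- cluster_permutation_paired(A, A), "zero-variance")
  expect_equal(nrow(ct$clusters), 0L)
  flat <- matrix(1 / 7, 6, 40)
  expect_warning(c2 <- cluster_permutation_vs_chance(flat), "zero-variance")
  expect_equal(nrow(c2$clusters), 0L)
})

test_that("n = 5 cluster p-values match exhaustive enumeration", {
  for (seed in c(7, 19)) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(5 * 25), 5) +
        rep(c(rep(0, 10), rep(1.2, 6), rep(0, 9)), each = 5)
    })
    ct <- cluster_permutation_paired(X, matrix(0, 5, 25))
    expect_true(ct$exhaustive)
    expect_equal(ct$n_permutations, 32L)
    oracle <- brute_cluster_p(X)
    expect_equal(nrow(ct$clusters), nrow(oracle))
    ord <- order(ct$clusters$start)
    expect_equal(ct$clusters$start[ord], oracle$start)
    expect_equal(ct$clusters$mass[ord], oracle$mass, tolerance = 1e-10)
    expect_equal(ct$clusters$p_value[ord], oracle$p, tolerance = 1e-12)
  }
})

test_that("one-sample cluster test detects an injected window", {
  withr::with_seed(3, {
    acc <- matrix(1 / 7 + rnorm(8 * 50, sd = 0.02), 8)
    acc[, 20:30] <- acc[, 20:30] + 0.1
  })
  ct <- cluster_permutation_vs_chance(acc, times = seq(0, 0.49, by = 0.01))
  sig <- significant_clusters(ct)
  expect_gte(nrow(sig), 1)
  expect_true(any(sig$start_time <= 0.25 & sig$end_time >= 0.25))
})

test_that("permutation p-values are invariant to subject order", {
  withr::with_seed(8, {
    A <- matrix(rnorm(7 * 30), 7) + rep(c(rep(0, 8), rep(1, 8), rep(0, 14)),
                                        each = 7)
    B <- matrix(rnorm(7 * 30), 7)
  })
  p1 <- cluster_permutation_paired(A, B)$clusters$p_value
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  p2 <- cluster_permutation_paired(A[perm, ], B[perm, ])$clusters$p_value
  expect_equal(p1, p2)
})

test_that("Monte-Carlo flips agree with exhaustive enumeration", {
  withr::with_seed(12, {
    X <- matrix(rnorm(10 * 30), 10) +
      rep(c(rep(0, 10), rep(0.9, 8), rep(0, 12)), each = 10)
  })
  exh <- cluster_permutation_paired(X, matrix(0, 10, 30))
  expect_true(exh$exhaustive)
  # Monte-Carlo on a larger stacked problem (n = 20 forces sampling)
  X2 <- rbind(X, X)
  mc <- cluster_permutation_paired(X2, matrix(0, 20, 30), n_perm = 4000)
  expect_false(mc$exhaustive)
  expect_true(all(mc$clusters$p_value > 0))
})

test_that("repeated-measures ANOVA matches hand sums of squares", {
  df <- tidyr::expand_grid(subject = 1:6, condition = c("a", "b", "c"))
  withr::with_seed(1, {
    df$value <- rnorm(18) + rep(c(0, 0.5, 1), 6)
  })
  es <- rm_anova_1way(df)
  Y <- matrix(df$value, 6, 3, byrow = TRUE)
  gm <- mean(Y)
  ss_cond <- 6 * sum((colMeans(Y) - gm)^2)
  ss_err <- sum((Y - outer(rowMeans(Y), colMeans(Y), "+") + gm)^2)
  f_hand <- (ss_cond / 2) / (ss_err / 10)
  expect_equal(es$statistic, f_hand, tolerance = 1e-10)
  expect_equal(es$df, c(2, 10))
  expect_equal(es$eta_p_sq, 2 * f_hand / (2 * f_hand + 10))

  # equal condition means with residual variance -> F = 0 exactly
  df0 <- tibble::tibble(
    subject = rep(1:3, each = 3),
    condition = rep(c("a", "b", "c"), 3),
    value = c(1, 2, 3, 2, 3, 1, 3, 1, 2)
  )
  expect_equal(rm_anova_1way(df0)$statistic, 0, tolerance = 1e-12)
  # incomplete design -> error
  expect_error(rm_anova_1way(df[-1, ]), class = "attnpipe_domain_error")
})

test_that("effect sizes recompute from the test statistics", {
  expect_equal(round(eta_p_sq_from_f(14.40, 3, 72), 2), 0.38)
  expect_equal(round(cohens_d_from_t(3.48, 25), 2), 0.70)
  a <- c(1, 2, 3, 4); b <- c(2, 2, 2, 5)
  es <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(es$statistic, t_hand, tolerance = 1e-12)
  expect_equal(es$df, 3)
  expect_equal(es$d, t_hand / 2)
  expect_warning(paired_t(a, a), "Zero-variance")
  same <- suppressWarnings(paired_t(a, a))
  expect_equal(same$statistic, 0)
  expect_equal(same$d, 0)
})

test_that("signal-detection measures use the log-linear correction", {
  sym <- sdt_measures(50, 50, 50, 50)
  expect_equal(sym$dprime, 0)
  expect_equal(sym$criterion, 0)
  # z(0.8413) = 1, z(0.1587) = -1 on uncorrected rates
  un <- sdt_measures(8413, 1587, 1587, 8413, correction = "none")
  expect_equal(un$dprime, 2, tolerance = 1e-3)
  # perfect performance stays finite under the correction
  perf <- sdt_measures(100, 0, 0, 100)
  expect_true(is.finite(perf$dprime))
  expect_gt(perf$dprime, 4)
  expect_error(sdt_measures(0, 0, 2, 3), class = "attnpipe_domain_error")
})

test_that("within-participant SEM removes between-subject variance", {
  # identical condition profiles with subject offsets -> zero SEM
  prof <- c(1, 2, 3)
  df <- tidyr::expand_grid(subject = 1:5, condition = c("a", "b", "c"))
  df$value <- rep(prof, 5) + rep(c(0, 10, -3, 7, 2), each = 3)
  out <- within_subject_sem(df)
  expect_equal(out$sem, rep(0, 3), tolerance = 1e-12)

  # k = 2 hand computation with the Morey factor sqrt(2)
  df2 <- tibble::tibble(subject = rep(1:3, each = 2),
                        condition = rep(c("a", "b"), 3),
                        value = c(1, 2, 4, 7, 2, 2))
  out2 <- within_subject_sem(df2)
  Y <- matrix(df2$value, 3, 2, byrow = TRUE)
  norm <- Y - rowMeans(Y) + mean(Y)
  hand <- apply(norm, 2, sd) / sqrt(3) * sqrt(2)
  expect_equal(out2$sem, hand, tolerance = 1e-12)

  # adding an offset to one subject changes nothing
  df3 <- df2; df3$value[df3$subject == 2] <- df3$value[df3$subject == 2] + 50
  expect_equal(within_subject_sem(df3)$sem, out2$sem, tolerance = 1e-12)
})

test_that("brain-behavior correlation behaves like Pearson's r", {
  x <- c(0.1, 0.3, 0.2, 0.5, 0.4)
  out <- brain_behavior_correlation(x, x)
  expect_equal(out$r, 1)
  expect_equal(out$df, 3)
  expect_error(brain_behavior_correlation(x, rep(1, 5)),
               class = "attnpipe_domain_error")
  expect_error(brain_behavior_correlation(x[1:3], x[1:3]),
               class = "attnpipe_domain_error")
  # null calibration: ~5% false positives
  withr::with_seed(2, {
    p <- replicate(1000, {
      brain_behavior_correlation(rnorm(12), rnorm(12))$p_value
    })
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})
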