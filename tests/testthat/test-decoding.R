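test_that("decoding preparation yields 100 Hz low-passed posterior data", {
  times <- seq(-0.5, 3.0, by = 1 / 500)
  n_t <- length(times)
  mk <- function(f) {
    data <- array(0, c(19, n_t, 2))
    for (c_i in 1:19) data[c_i, , ] <- sin(2 * pi * f * times)
    toy_epochs(data, srate = 500, times = times,
               channels = montage("posterior19"),
               meta = tibble::tibble(trial = 1:2))
  }
  prep <- prepare_for_decoding(mk(5))
  expect_equal(prep$srate, 100)
  expect_equal(dim(prep$data)[1], 17L) # posterior channels only
  expect_equal(dim(prep$data)[2], 350L)
  mid <- 60:300
  # 5 Hz passes, 30 Hz is attenuated by >= 15 dB
  g5 <- sd(prepare_for_decoding(mk(5))$data[1, mid, 1]) / sd(sin(2 * pi * 5 * times))
  g30 <- sd(prepare_for_decoding(mk(30))$data[1, mid, 1]) / sd(sin(2 * pi * 30 * times))
  expect_gt(g5, 0.85)
  expect_lt(20 * log10(g30), -15)
  # DC epochs pass through unchanged (up to edge effects and the
  # decimator's sub-percent passband ripple)
  dc <- mk(0); dc$data[] <- 3
  pdc <- prepare_for_decoding(dc)
  expect_lt(max(abs(pdc$data[, mid, ] - 3)) / 3, 0.02)
})

test_that("LDA matches the closed-form discriminant and MASS on toys", {
  withr::with_seed(3, {
    X <- rbind(matrix(rnorm(120, 0), ncol = 2),
               matrix(rnorm(120, 6), ncol = 2))
  })
  y <- rep(c("a", "b"), each = 60)
  fit <- train_lda(X, y, ridge = 0)
  expect_equal(mean(predict(fit, X) == y), 1) # separable toy
  # closed-form Fisher discriminant
  mu_a <- colMeans(X[y == "a", ]); mu_b <- colMeans(X[y == "b", ])
  Sp <- (crossprod(sweep(X[y == "a", ], 2, mu_a)) +
           crossprod(sweep(X[y == "b", ], 2, mu_b))) / (120 - 2)
  w <- solve(Sp, mu_b - mu_a)
  score <- X %*% w - sum((mu_a + mu_b) * w) / 2
  expect_equal(predict(fit, X) == "b", as.vector(score > 0))
  # independent cross-check against MASS
  skip_if_not_installed("MASS")
  mfit <- MASS::lda(X, grouping = factor(y))
  expect_equal(predict(fit, X),
               as.character(predict(mfit, X)$class))
})

test_that("LDA degenerate cases are handled", {
  # within-class variance only along the second feature: singular pooled
  # covariance unless the ridge is active
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
  y <- c("a", "a", "b", "b")
  expect_error(train_lda(X, y, ridge = 0), class = "attnpipe_numeric_error")
  expect_s3_class(train_lda(X, y, ridge = 1e-6), "lda_model")
  expect_error(train_lda(X[1:3, ], c("a", "a", "b")),
               class = "attnpipe_domain_error")
})

test_that("temporal decoding is deterministic and finds the signal window", {
  fx <- pattern_epochs(n_per_class = 6, amp = 4, seed = 2)
  r1 <- temporal_decode(fx$epochs, k = 3, iterations = 2, seed = 5)
  r2 <- temporal_decode(fx$epochs, k = 3, iterations = 2, seed = 5)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(attr(r1, "folds"), attr(r2, "folds"))
  expect_equal(attr(r1, "chance"), 1 / 7)
  sig <- mean(r1$accuracy[25:32])
  noisefloor <- mean(r1$accuracy[c(1:15, 45:60)])
  expect_gt(sig, 0.6)
  expect_lt(noisefloor, 0.35)
  expect_error(temporal_decode(fx$epochs, k = 10),
               class = "attnpipe_stratification_error")
})

test_that("shuffled labels decode at chance", {
  fx <- pattern_epochs(n_per_class = 6, amp = 4, seed = 3)
  shuffled <- withr::with_seed(9, sample(fx$labels))
  accs <- sapply(1:4, function(s) {
    mean(temporal_decode(fx$epochs, shuffled, k = 3, iterations = 1,
                         seed = s)$accuracy[25:32])
  })
  expect_lt(abs(mean(accs) - 1 / 7), 0.08)
})

test_that("cross-validated accuracy equals a brute-force fold replay", {
  fx <- pattern_epochs(n_per_class = 4, classes = c("red", "green", "blue"),
                       n_time = 6, amp = 2, seed = 4, sig_idx = 2:5,
                       channels = posterior_17[1:5])
  k <- 4 # leave-one-per-class folds
  res <- temporal_decode(fx$epochs, k = k, iterations = 1, seed = 11)
  folds <- attr(res, "folds")$fold
  # independent replay with the naive classifier
  for (t_i in c(2, 4)) {
    acc <- mean(sapply(seq_len(k), function(f) {
      tr <- folds != f
      X <- t(fx$epochs$data[, t_i, ])
      mean(naive_lda_predict(X[tr, ], fx$labels[tr], X[!tr, , drop = FALSE])
           == fx$labels[!tr])
    }))
    expect_equal(res$accuracy[t_i], acc)
  }
})

test_that("two-cue decoding averages two independent passes", {
  fx <- pattern_epochs(n_per_class = 4, classes = color_palette(),
                       n_time = 10, amp = 3, seed = 5, sig_idx = 3:8)
  n <- length(fx$labels)
  # both cue labels identical -> average equals a single pass
  meta <- tibble::tibble(
    trial = seq_len(n), target_color = fx$labels,
    cued_colors = purrr::map(fx$labels, function(l) {
      c(l, setdiff(color_palette(), l)[1])
    })
  )
  ep <- fx$epochs; ep$trial_meta <- meta
  lab_other <- vapply(seq_len(n), function(i) {
    setdiff(meta$cued_colors[[i]], meta$target_color[i])[1]
  }, character(1))
  r_two <- decode_two_cue_colors(ep, k = 3, iterations = 1, seed = 6)
  r_a <- temporal_decode(ep, meta$target_color, k = 3, iterations = 1,
                         seed = attnpipe:::child_seed(6, 1))
  r_b <- temporal_decode(ep, lab_other, k = 3, iterations = 1,
                         seed = attnpipe:::child_seed(6, 2))
  expect_equal(r_two$accuracy, (r_a$accuracy + r_b$accuracy) / 2)
  # trials lacking a second cue raise a labeling error
  ep_bad <- ep
  ep_bad$trial_meta$cued_colors[[1]] <- "red"
  expect_error(decode_two_cue_colors(ep_bad),
               class = "attnpipe_label_error")
})

test_that("accuracy smoothing is a mass-preserving centered moving mean", {
  mk <- function(acc) tibble::tibble(time = seq(0, by = 0.01,
                                                length.out = length(acc)),
                                     accuracy = acc)
  const <- smooth_accuracy(mk(rep(0.3, 50)), 0.04)
  expect_equal(const$accuracy, rep(0.3, 50))
  imp <- smooth_accuracy(mk(c(rep(0, 24), 1, rep(0, 25))), 0.04)
  expect_equal(sum(imp$accuracy > 0), 5) # 40 ms at 100 Hz spreads over 5
  expect_equal(sum(imp$accuracy), 1)
  ident <- smooth_accuracy(mk(runif(20)), 0.01) # one-sample window
  expect_equal(ident$accuracy, mk(ident$accuracy)$accuracy)
})
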