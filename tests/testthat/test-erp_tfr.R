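make_posterior_epochs <- function(data, srate = 500, times = NULL,
                                  meta = NULL) {
  toy_epochs(data, srate = srate, times = times, channels = posterior_17,
             meta = meta)
}

test_that("ERPs average trials then posterior electrodes", {
  set.seed(4)
  n_ch <- 17; n_t <- 100
  one <- array(rnorm(n_ch * n_t), c(n_ch, n_t, 1))
  ep <- make_posterior_epochs(one, meta = tibble::tibble(
    trial = 1L, cue_condition = "one", is_target = TRUE))
  erp <- compute_erp(ep)
  expect_equal(erp$amplitude, colMeans(one[, , 1]))

  # identical trials in two conditions -> zero condition difference
  dup <- array(rep(one, 2), c(n_ch, n_t, 2))
  ep2 <- make_posterior_epochs(dup, meta = tibble::tibble(
    trial = 1:2, cue_condition = c("one", "two"), is_target = TRUE))
  erp2 <- compute_erp(ep2)
  d <- erp2$amplitude[erp2$condition == "one"] -
    erp2$amplitude[erp2$condition == "two"]
  expect_equal(max(abs(d)), 0)

  # noise trials are excluded by default
  ep3 <- make_posterior_epochs(dup, meta = tibble::tibble(
    trial = 1:2, cue_condition = "one", is_target = c(TRUE, FALSE)))
  expect_equal(compute_erp(ep3)$amplitude, colMeans(one[, , 1]))

  expect_error(compute_erp(toy_epochs(one)), class = "attnpipe_config_error")
})

test_that("a known evoked bump is recovered by the ERP", {
  set.seed(5)
  n_tr <- 40; n_t <- 200
  times <- seq(-0.2, 0.195, length.out = n_t)
  bump <- 3 * exp(-(times - 0.1)^2 / (2 * 0.02^2))
  data <- array(rnorm(17 * n_t * n_tr, sd = 2), c(17, n_t, n_tr))
  data <- data + rep(bump, each = 17)
  ep <- make_posterior_epochs(data, meta = tibble::tibble(
    trial = 1:n_tr, cue_condition = "one", is_target = TRUE))
  erp <- compute_erp(ep)
  se <- 2 / sqrt(17 * n_tr)
  expect_lt(abs(max(erp$amplitude) - 3), 4 * se)
})

test_that("wavelet power peaks at the nearest center frequency", {
  bank <- gabor_bank()
  expect_equal(nrow(bank), 60L)
  expect_equal(range(bank$freq), c(2, 80))
  tt <- seq(0, 3, by = 1 / 500)
  ep <- toy_epochs(array(2 * sin(2 * pi * 10 * tt), c(1, length(tt), 1)),
                   srate = 500, times = tt,
                   meta = tibble::tibble(trial = 1L, cue_condition = "one"))
  tfr <- gabor_tfr(ep, bank)
  prof <- apply(tfr[1, 1, , 500:1000], 1, mean)
  expect_equal(which.max(prof), which.min(abs(bank$freq - 10)))
  # amplitude-A sinusoid -> power A^2/4 at the matched wavelet
  expect_equal(max(prof), 1, tolerance = 0.05)
  # zero signal -> zero power
  ep0 <- toy_epochs(array(0, c(1, length(tt), 1)), srate = 500, times = tt,
                    meta = tibble::tibble(trial = 1L, cue_condition = "one"))
  expect_equal(max(gabor_tfr(ep0, bank)), 0)
  expect_error(gabor_tfr(ep, gabor_bank(fmax = 400)),
               class = "attnpipe_domain_error")
})

test_that("white-noise power is flat after wavelet-energy correction", {
  set.seed(6)
  tt <- seq(0, 3, by = 1 / 500)
  ep <- toy_epochs(array(rnorm(length(tt) * 40), c(1, length(tt), 40)),
                   srate = 500, times = tt,
                   meta = tibble::tibble(trial = 1:40, cue_condition = "one"))
  bank <- gabor_bank()
  tw <- gabor_tfr(ep, bank)
  prof <- apply(tw[1, 1, , 250:1250], 1, mean) / bank$sd_f
  expect_lt(max(abs(10 * log10(prof / mean(prof)))), 1)
})

test_that("common-baseline dB normalization matches hand arithmetic", {
  mk_raw <- function(vals, nt = 100) {
    raw <- array(0, c(length(vals), 1, 2, nt))
    for (i in seq_along(vals)) raw[i, , , ] <- vals[i]
    attr(raw, "times") <- seq(-0.5, 0.49, length.out = nt)
    attr(raw, "freqs") <- c(5, 10)
    class(raw) <- "tfr_raw"
    raw
  }
  # equal power everywhere -> exactly 0 dB
  eq <- baseline_db(mk_raw(c(2, 2)))
  expect_equal(max(abs(eq)), 0)
  # conditions at 1 and 3 -> common baseline 2; condition 1 at -3.01 dB
  db <- baseline_db(mk_raw(c(1, 3)))
  expect_equal(db[1, 1, 1, 1], 10 * log10(1 / 2), tolerance = 1e-10)
  expect_equal(db[2, 1, 1, 1], 10 * log10(3 / 2), tolerance = 1e-10)
  # power = 10 x baseline -> +10 dB
  raw <- mk_raw(c(1, 1))
  raw[, , , 52:100] <- 10 # post-baseline samples only
  db10 <- baseline_db(raw)
  expect_equal(db10[1, 1, 1, 100], 10, tolerance = 1e-10)
  # invariant to global amplitude rescaling
  raw_a <- mk_raw(c(1, 3)); raw_b <- mk_raw(c(1, 3) * 4)
  expect_equal(baseline_db(raw_a)[1, 1, 1, 1], baseline_db(raw_b)[1, 1, 1, 1])
  expect_error(baseline_db(mk_raw(c(0, 0))),
               class = "attnpipe_numeric_error")
})

test_that("band power averages the alpha wavelets and finds suppression", {
  # flat TFR of value v -> constant time course v
  raw <- array(2, c(2, 1, 3, 50))
  attr(raw, "times") <- seq(0, 0.49, by = 0.01)
  attr(raw, "freqs") <- c(6, 10, 13)
  class(raw) <- "tfr_result"
  dimnames(raw) <- list(c("one", "two"), "Pz", NULL, NULL)
  tc <- band_power(raw, c(8, 14))
  expect_equal(unique(tc$power_db), 2)
  expect_error(band_power(raw, c(14, 8)), class = "attnpipe_domain_error")
  expect_error(band_power(raw, c(60, 70)), class = "attnpipe_domain_error")

  # -2 dB alpha suppression injected post-stimulus is recovered
  tt <- seq(-0.5, 2.0, by = 1 / 500)
  supp <- ifelse(tt > 0.2 & tt < 1.0, 10^(-2 / 20), 1)
  mk <- function(n_tr, seed) {
    withr::with_seed(seed, {
      arr <- array(0, c(1, length(tt), n_tr))
      for (i in seq_len(n_tr)) {
        arr[1, , i] <- 4 * supp * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)) +
          rnorm(length(tt), sd = 0.5)
      }
      arr
    })
  }
  data <- array(c(mk(12, 1), mk(12, 2)), c(1, length(tt), 24))
  ep <- toy_epochs(data, srate = 500, times = tt, channels = "Pz",
                   meta = tibble::tibble(trial = 1:24,
                                         cue_condition = rep(c("one", "two"),
                                                             each = 12)))
  tfr <- baseline_db(gabor_tfr(ep, gabor_bank(20, 4, 30)), c(-0.5, 0))
  tc2 <- band_power(tfr, c(8, 14))
  dip <- tc2 |> dplyr::filter(time > 0.45, time < 0.75)
  expect_equal(mean(dip$power_db), -2, tolerance = 0.3)
})
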