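test_that("re-referencing subtracts the TP9/TP10 mean and is idempotent", {
  set.seed(1)
  dat <- matrix(rnorm(4 * 100), 4)
  rec <- toy_record(dat, channels = c("TP9", "TP10", "Pz", "Oz"))
  # zero reference leaves the record unchanged
  rec0 <- rec; rec0$data[1:2, ] <- 0
  expect_equal(rereference(rec0)$data, rec0$data)
  # common-mode offset is rejected
  rec_c <- rec; rec_c$data <- rec_c$data + 7.3
  expect_equal(rereference(rec_c)$data, rereference(rec)$data)
  # two-channel hand oracle
  toy <- toy_record(rbind(c(1, 2, 3), c(3, 2, 1)),
                    channels = c("TP9", "TP10"))
  out <- rereference(toy)$data
  expect_equal(out[1, ], c(1, 2, 3) - c(2, 2, 2), ignore_attr = TRUE)
  # idempotence
  once <- rereference(rec)
  expect_equal(rereference(once)$data, once$data)
  expect_error(rereference(toy_record(dat)), class = "attnpipe_config_error")
})

test_that("band-pass and notch filtering meet their attenuation contracts", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  mid <- 1500:3500
  rec60 <- toy_record(matrix(sin(2 * pi * 60 * t), 1), srate = fs)
  out60 <- filter_continuous(rec60)$data[1, ]
  expect_lt(20 * log10(sd(out60[mid]) / sd(sin(2 * pi * 60 * t)[mid])), -20)
  rec10 <- toy_record(matrix(sin(2 * pi * 10 * t), 1), srate = fs)
  out10 <- filter_continuous(rec10)$data[1, ]
  gain10 <- sd(out10[mid]) / sd(sin(2 * pi * 10 * t)[mid])
  expect_lt(abs(gain10 - 1), 0.05)
  # DC handling: strongly reduced with a 1 Hz high-pass edge
  recdc <- toy_record(matrix(rep(5, length(t)), 1), srate = fs)
  outdc <- filter_continuous(recdc, band = c(1, 80))$data[1, ]
  expect_lt(max(abs(outdc[mid])), 0.05)
  expect_error(filter_continuous(recdc, band = c(0.01, 300)),
               class = "attnpipe_domain_error")
})

test_that("epoching indexes the record correctly and baselines to zero", {
  fs <- 500
  n <- 15 * fs
  x <- matrix(seq_len(n), 1) # ramp encodes the sample index
  rec <- toy_record(x, srate = fs, channels = "Pz",
                    events = tibble::tibble(trial = 1L, event = "cue",
                                            onset = 10),
                    schedule = tibble::tibble(trial = 1L))
  ep <- epoch_and_baseline(rec, "cue")
  expect_equal(dim(ep$data), c(1L, 1751L, 1L))
  # window [-0.5, 3] around t=10 s covers samples 9.5 s..13 s
  raw_seg <- x[1, (round(9.5 * fs) + 1):(round(13 * fs) + 1)]
  expect_equal(ep$data[1, , 1], raw_seg - mean(raw_seg[1:251]),
               ignore_attr = TRUE)
  # baseline window mean is zero
  expect_lt(abs(mean(ep$data[1, ep$times <= 0, 1])), 1e-9)

  # constant record -> all-zero epochs
  recc <- rec; recc$data[] <- 4.2
  epc <- epoch_and_baseline(recc, "cue")
  expect_equal(max(abs(epc$data)), 0)

  # a 5 uV step just after the lock onset survives baselining
  recs <- rec; recs$data[] <- 0
  recs$data[1, (round(10 * fs) + 2):n] <- 5
  eps <- epoch_and_baseline(recs, "cue")
  expect_equal(mean(eps$data[1, ep$times > 0.01, 1]), 5, tolerance = 1e-6)

  # events without coverage are dropped with a warning
  rec2 <- rec
  rec2$events <- tibble::tibble(trial = 1:2, event = "cue",
                                onset = c(10, 14.9))
  rec2$schedule <- tibble::tibble(trial = 1:2)
  expect_warning(ep2 <- epoch_and_baseline(rec2, "cue"), "coverage")
  expect_equal(dim(ep2$data)[3], 1L)
})

test_that("target-locked epochs use the early baseline window", {
  fs <- 500
  x <- matrix(rnorm(20 * fs), 1)
  rec <- toy_record(x, srate = fs, channels = "Pz",
                    events = tibble::tibble(trial = 1L, event = "target",
                                            onset = 10),
                    schedule = tibble::tibble(trial = 1L))
  ep <- epoch_and_baseline(rec, "target")
  expect_equal(range(ep$times), c(-2.1, 1.4))
  bl <- ep$data[1, ep$times >= -2.1 & ep$times <= -1.6, 1]
  expect_lt(abs(mean(bl)), 1e-9)
})

test_that("artifact rejection removes exactly the contaminated trials", {
  set.seed(2)
  data <- array(rnorm(3 * 100 * 30, sd = 10), c(3, 100, 30))
  bad <- c(4, 9, 23)
  data[2, 50, bad] <- 300
  ep <- toy_epochs(data, srate = 100, times = seq(-0.5, 0.49, by = 0.01))
  out <- reject_artifacts(ep, 200, c(-0.5, 0.49))
  expect_equal(which(out$rejection_mask), bad)
  expect_equal(dim(out$data)[3], 27L)
  expect_equal(attr(out, "rejection_fraction"), 0.1)
  # clean data: nothing rejected
  clean <- toy_epochs(array(rnorm(3 * 100 * 10), c(3, 100, 10)),
                      srate = 100, times = seq(-0.5, 0.49, by = 0.01))
  expect_equal(attr(reject_artifacts(clean, 200, c(-0.5, 0.49)),
                    "rejection_fraction"), 0)
  # infinite threshold disables rejection
  off <- reject_artifacts(ep, Inf, c(-0.5, 0.49))
  expect_false(any(off$rejection_mask))
  expect_error(reject_artifacts(ep, 200, c(-1, 0.5)),
               class = "attnpipe_domain_error")
})

test_that("rejection never depends on trial labels", {
  set.seed(3)
  data <- array(rnorm(2 * 50 * 20, sd = 80), c(2, 50, 20))
  meta <- tibble::tibble(trial = 1:20, target_color = sample(color_palette(),
                                                             20, TRUE))
  ep <- toy_epochs(data, srate = 100, times = seq(-0.25, 0.24, by = 0.01),
                   meta = meta)
  ep_shuf <- ep
  ep_shuf$trial_meta <- meta[sample(20), ]
  expect_equal(reject_artifacts(ep, 150, NULL)$rejection_mask,
               reject_artifacts(ep_shuf, 150, NULL)$rejection_mask)
})

test_that("resampling preserves band-limited content", {
  times <- seq(-0.5, 3.0, by = 1 / 500)
  ep <- toy_epochs(array(sin(2 * pi * 8 * times), c(1, length(times), 1)),
                   srate = 500, times = times)
  same <- resample_epochs(ep, 500)
  expect_identical(same$data, ep$data)
  down <- resample_epochs(ep, 100)
  expect_equal(dim(down$data)[2], 350L) # 3.5 s at 100 Hz
  expect_equal(down$srate, 100)
  ref <- sin(2 * pi * 8 * down$times)
  keep <- 20:330
  expect_gt(cor(down$data[1, keep, 1], ref[keep]), 0.999)
  expect_error(resample_epochs(ep, -5), class = "attnpipe_domain_error")
  expect_error(resample_epochs(ep, 1000), class = "attnpipe_domain_error")
})
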