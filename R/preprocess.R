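#' Re-reference a continuous record to the linked mastoid approximation
#'
#' Subtracts the sample-wise mean of the TP9 and TP10 channels from every
#' channel. Applying the operation twice equals applying it once.
#'
#' @param record An `eeg_record`.
#' @param reference_channels The two reference channel names.
#' @return The re-referenced `eeg_record`.
#' @export
rereference <- function(record, reference_channels = c("TP9", "TP10")) {
  idx <- match(reference_channels, record$channel_names)
  if (anyNA(idx)) {
    abort(paste0("Reference channel(s) missing: ",
                 paste(reference_channels[is.na(idx)], collapse = ", ")),
          class = "attnpipe_config_error")
  }
  ref <- colMeans(record$data[idx, , drop = FALSE])
  record$data <- sweep(record$data, 2, ref, "-")
  record
}

zero_phase <- function(flt, x) as.numeric(signal::filtfilt(flt, x))

#' Zero-phase band-pass and notch filtering of a continuous record
#'
#' Band-pass with half-amplitude cutoffs at `band` Hz: second-order
#' Butterworth high-pass and low-pass sections applied forward-backward
#' (12 dB/octave per pass direction; the forward-backward square turns
#' the -3 dB Butterworth point into the half-amplitude point). Line noise
#' is removed with a zero-phase band-stop at `notch` +/- 2 Hz.
#'
#' @param record An `eeg_record`.
#' @param band Half-amplitude cutoffs in Hz (default `c(0.01, 80)`).
#' @param notch Line frequency in Hz (`NULL` disables; default 60).
#' @return The filtered `eeg_record` (same length as the input).
#' @export
filter_continuous <- function(record, band = c(0.01, 80), notch = 60) {
  fs <- record$srate
  nyq <- fs / 2
  if (band[2] >= nyq || (!is.null(notch) && notch >= nyq)) {
    abort("Filter cutoff at or above the Nyquist frequency.",
          class = "attnpipe_domain_error")
  }
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  lp <- signal::butter(2, band[2] / nyq, type = "low")
  bs <- if (!is.null(notch)) {
    signal::butter(2, c(notch - 2, notch + 2) / nyq, type = "stop")
  }
  for (c_i in seq_len(nrow(record$data))) {
    x <- record$data[c_i, ]
    x <- zero_phase(hp, x)
    x <- zero_phase(lp, x)
    if (!is.null(bs)) x <- zero_phase(bs, x)
    record$data[c_i, ] <- x
  }
  record
}

#' Epoch a continuous record and subtract the baseline
#'
#' Cuts fixed windows around the lock events and subtracts, per channel
#' and per trial, the mean over the baseline window. Defaults follow the
#' analysis design: cue-locked 3.5-s epochs `[-0.5, 3.0]` s with baseline
#' `[-0.5, 0]` s; target-locked epochs `[-2.1, 1.4]` s with baseline
#' `[-2.1, -1.6]` s (approximately the cue-locked baseline period given
#' the cue-to-stimulus jitter). Events without full window coverage are
#' dropped with a warning.
#'
#' @param record An `eeg_record` with an `events` table.
#' @param lock `"cue"` or `"target"`.
#' @param window Epoch window in seconds relative to the lock event;
#'   `NULL` uses the lock-specific default above.
#' @param baseline_window Baseline interval; `NULL` uses the default.
#' @return An `epoch_set`.
#' @export
epoch_and_baseline <- function(record, lock = c("cue", "target"),
                               window = NULL, baseline_window = NULL) {
  lock <- match.arg(lock)
  if (is.null(window)) {
    window <- if (lock == "cue") c(-0.5, 3.0) else c(-2.1, 1.4)
  }
  if (is.null(baseline_window)) {
    baseline_window <- if (lock == "cue") c(-0.5, 0) else c(-2.1, -1.6)
  }
  fs <- record$srate
  ev <- record$events[record$events$event == lock, ]
  n_len <- round((window[2] - window[1]) * fs) + 1L
  times <- window[1] + (seq_len(n_len) - 1) / fs
  starts <- round((ev$onset + window[1]) * fs) + 1L
  ok <- starts >= 1 & (starts + n_len - 1L) <= ncol(record$data)
  if (any(!ok)) {
    warn(sprintf("Dropping %d event(s) without full epoch coverage.",
                 sum(!ok)))
  }
  starts <- starts[ok]
  data <- array(0, c(nrow(record$data), n_len, length(starts)))
  for (i in seq_along(starts)) {
    data[, , i] <- record$data[, starts[i] + seq_len(n_len) - 1L]
  }
  meta <- record$schedule[match(ev$trial[ok], record$schedule$trial), ]
  ep <- new_epochs(data, fs, times, lock, record$channel_names, meta)
  baseline_epochs(ep, baseline_window)
}

#' @rdname epoch_and_baseline
#' @param epochs An `epoch_set`.
#' @export
baseline_epochs <- function(epochs, baseline_window) {
  sel <- epochs$times >= baseline_window[1] - 1e-9 &
    epochs$times <= baseline_window[2] + 1e-9
  if (!any(sel)) abort("Baseline window outside the epoch.",
                       class = "attnpipe_domain_error")
  bl <- apply(epochs$data[, sel, , drop = FALSE], c(1, 3), mean)
  d <- dim(epochs$data)
  epochs$data <- epochs$data - aperm(
    array(bl, c(d[1], d[3], d[2])), c(1, 3, 2)
  )
  epochs
}

#' Threshold-based artifact rejection
#'
#' Removes every trial in which any channel's absolute voltage exceeds
#' `threshold` microvolts inside `check_window`. The rejection decision
#' never consults trial labels.
#'
#' @param epochs An `epoch_set`.
#' @param threshold Rejection threshold in microvolts (default 200).
#' @param check_window Interval checked, in seconds relative to the lock
#'   event (default `[-0.5, 2]` clipped to the cue-locked epoch; `NULL`
#'   checks the whole epoch). Must lie inside the epoch window.
#' @return The cleaned `epoch_set`; `rejection_mask` marks removed trials
#'   and `attr(, "rejection_fraction")` records the fraction removed.
#' @export
reject_artifacts <- function(epochs, threshold = 200,
                             check_window = c(-0.5, 2)) {
  if (is.null(check_window)) {
    sel <- rep(TRUE, length(epochs$times))
  } else {
    if (check_window[1] < min(epochs$times) - 1e-9 ||
        check_window[2] > max(epochs$times) + 1e-9) {
      abort("`check_window` must lie inside the epoch window.",
            class = "attnpipe_domain_error")
    }
    sel <- epochs$times >= check_window[1] - 1e-9 &
      epochs$times <= check_window[2] + 1e-9
  }
  mx <- apply(abs(epochs$data[, sel, , drop = FALSE]), 3, max)
  bad <- is.finite(threshold) & mx > threshold
  out <- select_trials(epochs, !bad)
  out$rejection_mask <- bad
  attr(out, "rejection_fraction") <- mean(bad)
  out
}

# FFT-based resampling of one or more columns (series along rows of `x`).
fft_resample_matrix <- function(x, n_out) {
  n_in <- nrow(x)
  if (n_out == n_in) return(x)
  X <- stats::mvfft(x)
  Y <- matrix(0 + 0i, n_out, ncol(x))
  kmax <- min((n_out - 1) %/% 2, (n_in - 1) %/% 2)
  Y[1, ] <- X[1, ]
  if (kmax >= 1) {
    Y[2:(kmax + 1), ] <- X[2:(kmax + 1), ]
    Y[(n_out - kmax + 1):n_out, ] <- X[(n_in - kmax + 1):n_in, ]
  }
  Re(stats::mvfft(Y, inverse = TRUE)) / n_in
}

#' Resample an epoch set
#'
#' For integer decimation factors each series is low-pass filtered
#' (zero-phase order-8 Chebyshev, via [signal::decimate()]) and
#' subsampled on the original sample grid; other ratios fall back to
#' Fourier-domain resampling (spectrum truncation). Both are
#' anti-aliased; the time axis is recomputed from the first sample and
#' the output holds `round(n * new_rate / srate)` samples.
#'
#' @param epochs An `epoch_set`.
#' @param new_rate Target sampling rate in Hz (must not exceed the current
#'   rate).
#' @return The resampled `epoch_set`.
#' @export
resample_epochs <- function(epochs, new_rate) {
  if (new_rate <= 0) abort("`new_rate` must be positive.",
                           class = "attnpipe_domain_error")
  if (new_rate > epochs$srate) {
    abort("Upsampling is not supported.", class = "attnpipe_domain_error")
  }
  if (new_rate == epochs$srate) return(epochs)
  d <- dim(epochs$data)
  n_out <- round(d[2] * new_rate / epochs$srate)
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), d[2], d[1] * d[3])
  q <- epochs$srate / new_rate
  if (q == round(q)) {
    res <- apply(flat, 2, function(x) {
      signal::decimate(x, q)[seq_len(n_out)]
    })
  } else {
    res <- fft_resample_matrix(flat, n_out)
  }
  epochs$data <- aperm(array(res, c(n_out, d[1], d[3])), c(2, 1, 3))
  epochs$times <- epochs$times[1] + (seq_len(n_out) - 1) / new_rate
  epochs$srate <- new_rate
  dimnames(epochs$data) <- list(epochs$channel_names, NULL, NULL)
  epochs
}

#' Full preprocessing chain for one continuous record
#'
#' Enforces the canonical order: re-reference, filter, epoch + baseline,
#' artifact rejection.
#'
#' @inheritParams epoch_and_baseline
#' @inheritParams reject_artifacts
#' @param band,notch Passed to [filter_continuous()].
#' @return A clean `epoch_set`.
#' @export
preprocess_record <- function(record, lock = "cue", band = c(0.01, 80),
                              notch = 60, threshold = 200,
                              check_window = NULL) {
  record <- rereference(record)
  record <- filter_continuous(record, band, notch)
  epochs <- epoch_and_baseline(record, lock)
  if (is.null(check_window)) {
    check_window <- if (lock == "cue") c(-0.5, 2) else range(epochs$times)
  }
  reject_artifacts(epochs, threshold, check_window)
}
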