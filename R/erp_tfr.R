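#' Condition ERPs over the posterior electrode cluster
#'
#' Per condition: average over (target) trials, then over the 17 posterior
#' electrodes. Both means commute, but the order is fixed for
#' definiteness.
#'
#' @param epochs An `epoch_set`.
#' @param electrode_set Electrodes to average over (default the posterior
#'   17); an error lists any missing names.
#' @param condition_col Metadata column defining the conditions.
#' @param target_only Keep only target trials (the analysis default).
#' @return An `erp_result` tibble: `condition`, `time`, `amplitude` (uV).
#' @export
compute_erp <- function(epochs, electrode_set = posterior_17,
                        condition_col = "cue_condition",
                        target_only = TRUE) {
  if (target_only && "is_target" %in% names(epochs$trial_meta)) {
    epochs <- select_trials(epochs, epochs$trial_meta$is_target)
  }
  epochs <- select_channels(epochs, electrode_set)
  conds <- epochs$trial_meta[[condition_col]]
  out <- purrr::map(sort(unique(conds)), function(cond) {
    sub <- epochs$data[, , conds == cond, drop = FALSE]
    trial_mean <- apply(sub, c(1, 2), mean) # channels x time
    tibble(condition = cond, time = epochs$times,
           amplitude = colMeans(trial_mean))
  }) |> dplyr::bind_rows()
  structure(out, electrode_set = electrode_set,
            class = c("erp_result", class(out)))
}

#' Gabor wavelet bank
#'
#' `n` log-spaced center frequencies between `fmin` and `fmax`, each with
#' a Gaussian spectral envelope of width `sd_f = f / cycles_factor`
#' (about 5-cycle wavelets with the default factor 5) and unit peak
#' spectral amplitude.
#'
#' @param n Number of wavelets (default 60).
#' @param fmin,fmax Frequency range in Hz (defaults 2 and 80).
#' @param cycles_factor Ratio of center frequency to spectral SD.
#' @return A tibble with `freq` and `sd_f`.
#' @export
gabor_bank <- function(n = 60, fmin = 2, fmax = 80, cycles_factor = 5) {
  freq <- exp(seq(log(fmin), log(fmax), length.out = n))
  tibble(freq = freq, sd_f = freq / cycles_factor)
}

#' Gabor-wavelet spectral power
#'
#' Convolves every trial and channel with each wavelet (frequency-domain
#' multiplication with a Gaussian spectral window of unit peak
#' amplitude, so a sinusoid of amplitude A at a wavelet's center yields
#' power A^2/4), squares the complex magnitude, and averages over trials
#' within each condition. Averaging single-trial power keeps total
#' (evoked + induced) power. With this normalization a wavelet's energy
#' grows with its bandwidth (proportional to frequency for a constant-Q
#' bank), so broadband-noise power rises with frequency; dividing by the
#' bank's energies (`sd_f`) flattens it.
#'
#' @param epochs An `epoch_set` (typically restricted to the posterior
#'   channels first).
#' @param bank A [gabor_bank()] tibble.
#' @param condition_col Metadata column defining the conditions.
#' @return A `tfr_raw` object: array `condition x channel x freq x time`
#'   of raw power (uV^2), with `freqs` and `times` attributes.
#' @export
gabor_tfr <- function(epochs, bank = gabor_bank(),
                      condition_col = "cue_condition") {
  fs <- epochs$srate
  if (max(bank$freq) >= fs / 2) {
    abort("Wavelet center frequency at or above Nyquist.",
          class = "attnpipe_domain_error")
  }
  d <- dim(epochs$data)
  n <- d[2]
  nfft <- stats::nextn(n, 2)
  fgrid <- (seq_len(nfft) - 1) * fs / nfft # 0 .. fs, wraps
  conds <- sort(unique(epochs$trial_meta[[condition_col]]))
  out <- array(0, c(length(conds), d[1], nrow(bank), n),
               dimnames = list(conds, epochs$channel_names, NULL, NULL))
  # analytic spectral windows, unit peak amplitude at the center frequency
  wins <- lapply(seq_len(nrow(bank)), function(k) {
    w <- exp(-(fgrid - bank$freq[k])^2 / (2 * bank$sd_f[k]^2))
    w[fgrid > fs / 2] <- 0 # analytic: positive frequencies only
    w
  })
  for (ci in seq_along(conds)) {
    keep <- which(epochs$trial_meta[[condition_col]] == conds[ci])
    flat <- matrix(0, nfft, d[1] * length(keep))
    flat[seq_len(n), ] <- matrix(
      aperm(epochs$data[, , keep, drop = FALSE], c(2, 1, 3)), n)
    X <- stats::mvfft(flat)
    for (k in seq_len(nrow(bank))) {
      conv <- stats::mvfft(X * wins[[k]], inverse = TRUE)[seq_len(n), ,
                                                          drop = FALSE] / nfft
      pow <- Mod(conv)^2
      # mean over trials, per channel
      pc <- array(pow, c(n, d[1], length(keep)))
      out[ci, , k, ] <- t(apply(pc, c(1, 2), mean))
    }
  }
  structure(out, freqs = bank$freq, times = epochs$times, srate = fs,
            class = "tfr_raw")
}

#' Common-baseline dB normalization of raw wavelet power
#'
#' The baseline-window power is averaged over time within each condition,
#' then across conditions, per frequency (and channel): the *common
#' baseline*. Every condition's power is divided by it and converted to
#' dB (`10 * log10`). A condition whose raw power equals the common
#' baseline is exactly 0 dB, and the result is invariant to global
#' amplitude rescaling of the record.
#'
#' @param raw A `tfr_raw` array from [gabor_tfr()] (needs >= 2
#'   conditions).
#' @param baseline_window Baseline interval in seconds (default
#'   `[-0.5, 0]`).
#' @return A `tfr_result` array (same shape, dB units).
#' @export
baseline_db <- function(raw, baseline_window = c(-0.5, 0)) {
  stopifnot(inherits(raw, "tfr_raw"))
  times <- attr(raw, "times")
  sel <- times >= baseline_window[1] - 1e-9 &
    times <= baseline_window[2] + 1e-9
  if (dim(raw)[1] < 2) abort("Need at least 2 conditions.",
                             class = "attnpipe_domain_error")
  # per-condition time-mean over baseline, then cross-condition mean
  bl_cond <- apply(raw[, , , sel, drop = FALSE], c(1, 2, 3), mean)
  common <- apply(bl_cond, c(2, 3), mean) # channel x freq
  if (any(common <= 0)) abort("Zero or negative baseline power.",
                              class = "attnpipe_numeric_error")
  out <- raw
  d <- dim(raw)
  common_arr <- array(common, c(d[2], d[3], d[4])) # recycled over time
  for (ci in seq_len(d[1])) {
    out[ci, , , ] <- 10 * log10(
      array(raw[ci, , , , drop = FALSE], d[-1]) / common_arr
    )
  }
  class(out) <- "tfr_result"
  attributes(out)[c("freqs", "times", "srate")] <-
    attributes(raw)[c("freqs", "times", "srate")]
  out
}

#' Band power time course
#'
#' Mean dB power over the wavelets whose centers fall inside `band`, then
#' over the requested electrodes.
#'
#' @param tfr A `tfr_result` from [baseline_db()].
#' @param band Frequency band in Hz (default alpha, `c(8, 14)`).
#' @param electrode_set Electrodes to average (default all present).
#' @return A tibble: `condition`, `time`, `power_db`.
#' @export
band_power <- function(tfr, band = c(8, 14), electrode_set = NULL) {
  if (band[2] < band[1]) abort("`band` must be increasing.",
                               class = "attnpipe_domain_error")
  freqs <- attr(tfr, "freqs")
  sel_f <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel_f) == 0) abort("No wavelet centers inside `band`.",
                                class = "attnpipe_domain_error")
  chans <- dimnames(tfr)[[2]]
  sel_c <- if (is.null(electrode_set)) seq_along(chans) else {
    idx <- match(electrode_set, chans)
    if (anyNA(idx)) abort("Missing electrodes in TFR.",
                          class = "attnpipe_config_error")
    idx
  }
  conds <- dimnames(tfr)[[1]]
  purrr::map(seq_along(conds), function(ci) {
    sub <- tfr[ci, sel_c, sel_f, , drop = FALSE]
    tibble(condition = conds[ci], time = attr(tfr, "times"),
           power_db = apply(sub, 4, mean))
  }) |> dplyr::bind_rows()
}
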