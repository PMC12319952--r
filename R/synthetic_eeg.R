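#' Generator parameters for synthetic scalp EEG
#'
#' Describes the statistical structure the analysis pipeline assumes:
#' 1/f background noise, a posterior alpha rhythm with event-related
#' suppression after each visual onset, a color-specific evoked spatial
#' pattern whose amplitude is scaled by an attentional gain that decreases
#' with the number of cued colors, and a cue-color pattern during cue
#' display and the preparatory period.
#'
#' Gains are in microvolts of pattern amplitude per unit coherence excess
#' (coherence minus the 0.2 noise floor); with the default one-cue gain of
#' 20 uV and a threshold-level coherence of ~0.45 the evoked component
#' peaks near 5 uV, a realistic visual-ERP scale against the ~8 uV 1/f
#' background.
#'
#' @param channels Character vector of channel names (default: the full
#'   64-channel cap).
#' @param srate Sampling rate in Hz.
#' @param noise_exponent,noise_scale 1/f background: spectral exponent
#'   (power ~ 1/f^exponent) and per-channel SD in microvolts.
#' @param alpha_freq,alpha_amplitude Posterior alpha center frequency (Hz)
#'   and amplitude (uV).
#' @param alpha_suppression Fractional amplitude suppression (0-1) of the
#'   alpha rhythm following each visual onset.
#' @param evoked_gain Named vector mapping cue condition to the gain `g_k`
#'   of the target-color evoked pattern; defaults decrease with the number
#'   of cued colors (`one > two >= three`).
#' @param evoked_latency,evoked_width Peak latency and FWHM (seconds) of
#'   the Gaussian temporal bump carrying the evoked pattern.
#' @param cue_signal_gain,prep_signal_gain Gain of the cue-color pattern
#'   during the 0.5-s cue display and during the ensuing preparatory
#'   period. With two cues, each color's pattern is presented at half
#'   gain (fixed total cue-display energy).
#' @param blink_rate Blink artifacts per minute (0 disables); blinks are
#'   ~350 uV frontal deflections that the 200-uV rejection rule removes.
#' @param subject_seed Seed for the subject-specific color topographies.
#' @return A `generator_params` list.
#' @export
generator_params <- function(channels = montage_64(), srate = 500,
                             noise_exponent = 1, noise_scale = 8,
                             alpha_freq = 10, alpha_amplitude = 5,
                             alpha_suppression = 0.5,
                             evoked_gain = c(no = 0, one = 20, two = 10,
                                             three = 6),
                             evoked_latency = 0.3, evoked_width = 0.1,
                             cue_signal_gain = 12, prep_signal_gain = 2,
                             blink_rate = 0, subject_seed = 1) {
  stopifnot(all(evoked_gain >= 0), srate > 2 * 80,
            alpha_suppression >= 0, alpha_suppression <= 1)
  if (!all(c("TP9", "TP10") %in% channels)) {
    abort("Montage must include the TP9/TP10 reference channels.",
          class = "attnpipe_config_error")
  }
  structure(
    list(
      channels = channels, srate = srate,
      noise_exponent = noise_exponent, noise_scale = noise_scale,
      alpha_freq = alpha_freq, alpha_amplitude = alpha_amplitude,
      alpha_suppression = alpha_suppression,
      evoked_gain = evoked_gain,
      evoked_latency = evoked_latency, evoked_width = evoked_width,
      cue_signal_gain = cue_signal_gain, prep_signal_gain = prep_signal_gain,
      blink_rate = blink_rate, subject_seed = subject_seed
    ),
    class = "generator_params"
  )
}

# FFT-shaped 1/f noise, unit-variance then scaled. Synthesized at the
# next power-of-two length and truncated: arbitrary lengths can have
# large prime factors that degrade the mixed-radix FFT badly, and a
# truncated stationary realization has the same spectrum.
one_over_f_noise <- function(n, srate, exponent, scale) {
  nfft <- stats::nextn(n, 2)
  f <- seq(0, srate / 2, length.out = nfft %/% 2 + 1)
  shape <- c(0, f[-1]^(-exponent / 2)) # kill DC
  half <- (rnorm(nfft %/% 2 + 1) + 1i * rnorm(nfft %/% 2 + 1)) * shape
  half[1] <- 0
  if (nfft %% 2 == 0) half[length(half)] <- Re(half[length(half)])
  spec <- c(half, Conj(rev(half[2:(length(half) - (1 - nfft %% 2))])))
  x <- Re(fft(spec, inverse = TRUE)) / nfft
  x <- x / sd(x)
  x[seq_len(n)] * scale
}

gaussian_bump <- function(t, latency, fwhm) {
  sdv <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(t - latency)^2 / (2 * sdv^2))
}

#' Subject-specific color topography
#'
#' Returns a fixed, unit-norm channel-weight vector for a color,
#' concentrated on the 17 posterior channels (frontal/posterior energy
#' ratio < 0.3). The seven color vectors of a subject are guaranteed
#' mutually non-collinear (pairwise |cosine| < 0.95); the construction is
#' a pure function of `(subject_seed, channels)`.
#'
#' @param color A palette color, or `NULL` for the full 7-column matrix.
#' @param subject_seed Integer subject seed.
#' @param channels Montage channel names.
#' @return A numeric weight vector (or channels x 7 matrix) named by
#'   channel.
#' @export
color_topography <- function(color = NULL, subject_seed = 1,
                             channels = montage_64()) {
  post <- match(posterior_17, channels)
  if (anyNA(post)) {
    abort(paste0("Montage is missing posterior channels: ",
                 paste(posterior_17[is.na(post)], collapse = ", ")),
          class = "attnpipe_config_error")
  }
  palette <- color_palette()
  draw_all <- function(attempt) {
    with_rng(child_seed(subject_seed, 17, attempt), {
      W <- matrix(0, length(channels), length(palette),
                  dimnames = list(channels, palette))
      for (j in seq_along(palette)) {
        w <- rnorm(length(channels), sd = 0.12)
        w[post] <- rnorm(length(post))
        W[, j] <- w / sqrt(sum(w^2))
      }
      W
    })
  }
  attempt <- 0L
  repeat {
    W <- draw_all(attempt)
    cosines <- abs(crossprod(W))
    diag(cosines) <- 0
    if (max(cosines) < 0.95) break
    attempt <- attempt + 1L
  }
  if (is.null(color)) return(W)
  if (!color %in% palette) {
    abort("Unknown color label.", class = "attnpipe_config_error")
  }
  W[, color]
}

#' Simulate a continuous EEG session for one subject
#'
#' Produces a continuous multichannel record (microvolts) with cue and
#' target event markers. Each trial contains: the cued color pattern(s)
#' during cue display (half gain per color with two cues) plus a weaker
#' sustained preparatory pattern until stimulus onset; on target trials a
#' target-color evoked component
#' `topography * g_k * Gaussian bump * (coherence - 0.2)`; 1/f background
#' noise on every channel; a posterior alpha rhythm suppressed after each
#' visual onset; and optional blink artifacts. The output is a pure
#' function of `(params, schedule, seed)`.
#'
#' @param schedule A `trial_schedule` tibble (see [build_eeg_schedule()]).
#' @param params A [generator_params()] list.
#' @param seed Integer seed for the noise and artifact streams.
#' @return An `eeg_record`: list with `data` (channels x samples matrix),
#'   `srate`, `channel_names`, `events` (tibble: `trial`, `event`
#'   (cue/target), `onset`) and the `schedule`.
#' @export
simulate_session <- function(schedule, params = generator_params(),
                             seed = 1) {
  stopifnot(inherits(params, "generator_params"))
  ch <- params$channels
  fs <- params$srate
  n_ch <- length(ch)
  dur <- max(schedule$stim_onset) + 2.5
  n_s <- ceiling(dur * fs)
  tvec <- (seq_len(n_s) - 1) / fs
  topo <- color_topography(NULL, params$subject_seed, ch)
  post <- match(posterior_17, ch)

  # sample-index range for a time interval [from, to)
  span <- function(from, to) {
    i0 <- max(1L, floor(from * fs) + 1L)
    i1 <- min(n_s, ceiling(to * fs) + 1L)
    if (i1 < i0) integer() else i0:i1
  }
  with_rng(seed, {
    data <- matrix(0, n_ch, n_s)
    for (c_i in seq_len(n_ch)) {
      data[c_i, ] <- one_over_f_noise(n_s, fs, params$noise_exponent,
                                      params$noise_scale)
    }

    # posterior alpha with event-related suppression
    if (params$alpha_amplitude > 0) {
      env <- rep(1, n_s)
      onsets <- c(schedule$onset, schedule$stim_onset)
      for (on in onsets) {
        idx <- span(on, on + 1.2)
        env[idx] <- env[idx] -
          params$alpha_suppression * gaussian_bump(tvec[idx], on + 0.4, 0.5)
      }
      env <- pmax(env, 0)
      for (c_i in post) {
        phase <- runif(1, 0, 2 * pi)
        data[c_i, ] <- data[c_i, ] + params$alpha_amplitude * env *
          sin(2 * pi * params$alpha_freq * tvec + phase)
      }
    }

    conds <- schedule$cue_condition
    for (i in seq_len(nrow(schedule))) {
      on_cue <- schedule$onset[i]
      on_stim <- schedule$stim_onset[i]
      cued <- schedule$cued_colors[[i]]
      # cue display + preparatory template signal
      if (length(cued) > 0 &&
          (params$cue_signal_gain > 0 || params$prep_signal_gain > 0)) {
        idx <- span(on_cue, on_stim)
        tt <- tvec[idx] - on_cue
        profile <- params$cue_signal_gain *
          gaussian_bump(tt, params$evoked_latency, params$evoked_width) +
          params$prep_signal_gain * as.numeric(tt >= 0.5 & tt < on_stim -
                                                 on_cue)
        w <- rowSums(topo[, cued, drop = FALSE]) / length(cued)
        data[, idx] <- data[, idx] + outer(w, profile)
      }
      # target-evoked component
      g <- unname(params$evoked_gain[conds[i]])
      if (isTRUE(schedule$is_target[i]) && is.finite(g) && g > 0) {
        idx <- span(on_stim, on_stim + 0.7)
        amp <- g * (schedule$coherence[i] - 0.2) *
          gaussian_bump(tvec[idx] - on_stim, params$evoked_latency,
                        params$evoked_width)
        data[, idx] <- data[, idx] +
          outer(topo[, schedule$target_color[i]], amp)
      }
    }

    # blink artifacts: frontal, large, rejectable
    if (params$blink_rate > 0) {
      n_blinks <- stats::rpois(1, params$blink_rate * dur / 60)
      if (n_blinks > 0) {
        fr <- match(frontal_channels(ch), ch)
        w <- rep(0.05, n_ch)
        w[fr] <- 1
        w["Fp1" == ch | "Fp2" == ch] <- 1.5
        for (b in seq_len(n_blinks)) {
          t0 <- runif(1, 0.5, dur - 0.5)
          idx <- span(t0 - 0.3, t0 + 0.3)
          data[, idx] <- data[, idx] +
            outer(w, 350 * gaussian_bump(tvec[idx], t0, 0.15))
        }
      }
    }

    rownames(data) <- ch
    events <- dplyr::bind_rows(
      tibble(trial = schedule$trial, event = "cue", onset = schedule$onset),
      tibble(trial = schedule$trial, event = "target",
             onset = schedule$stim_onset)
    ) |> dplyr::arrange(.data$onset)
    structure(
      list(data = data, srate = fs, channel_names = ch, events = events,
           schedule = schedule),
      class = "eeg_record"
    )
  })
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$srate,
              ncol(x$data) / x$srate, nrow(x$events)))
  invisible(x)
}
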