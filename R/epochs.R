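#' Epoch container
#'
#' Voltage epochs as a channels x time x trials array with a uniform time
#' axis relative to the lock event (cue or target onset), the per-trial
#' metadata as a tibble, and the rejection mask over the originally
#' epoched trials.
#'
#' @param data Numeric array `channels x samples x trials` (microvolts).
#' @param srate Sampling rate (Hz).
#' @param times Time axis in seconds relative to the lock event.
#' @param lock `"cue"` or `"target"`.
#' @param channel_names Channel labels (length = `dim(data)[1]`).
#' @param trial_meta Tibble with one row per retained trial.
#' @param rejection_mask Logical vector over the *original* trials
#'   (`TRUE` = rejected).
#' @return An `epoch_set` object.
#' @export
new_epochs <- function(data, srate, times, lock, channel_names, trial_meta,
                       rejection_mask = rep(FALSE, dim(data)[3])) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(channel_names),
            dim(data)[2] == length(times),
            dim(data)[3] == nrow(trial_meta),
            lock %in% c("cue", "target"))
  dt <- diff(times)
  stopifnot(all(dt > 0), max(abs(dt - 1 / srate)) < 1e-6 / srate + 1e-9)
  dimnames(data) <- list(channel_names, NULL, NULL)
  structure(
    list(data = data, srate = srate, times = times, lock = lock,
         channel_names = channel_names, trial_meta = trial_meta,
         rejection_mask = rejection_mask),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d channels x %d samples x %d trials @ %g Hz, %s-locked [%.2f, %.2f] s (%d rejected)\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$srate, x$lock,
    min(x$times), max(x$times), sum(x$rejection_mask)))
  invisible(x)
}

#' Restrict an epoch set to a channel subset
#'
#' @param epochs An `epoch_set`.
#' @param channels Channel names to keep (order preserved as given).
#' @return An `epoch_set` over the requested channels.
#' @export
select_channels <- function(epochs, channels = posterior_17) {
  idx <- match(channels, epochs$channel_names)
  if (anyNA(idx)) {
    abort(paste0("Missing channels: ",
                 paste(channels[is.na(idx)], collapse = ", ")),
          class = "attnpipe_config_error")
  }
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$channel_names <- channels
  epochs
}

#' Restrict an epoch set to a trial subset
#'
#' @param epochs An `epoch_set`.
#' @param keep Logical or integer index over retained trials.
#' @return An `epoch_set` over the requested trials.
#' @export
select_trials <- function(epochs, keep) {
  if (is.logical(keep)) keep <- which(keep)
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$trial_meta <- epochs$trial_meta[keep, ]
  epochs
}

#' Restrict an epoch set to a time window
#'
#' @param epochs An `epoch_set`.
#' @param window Two-element window in seconds (inclusive).
#' @return An `epoch_set` cropped to the window.
#' @export
crop_epochs <- function(epochs, window) {
  sel <- epochs$times >= window[1] - 1e-9 & epochs$times <= window[2] + 1e-9
  if (!any(sel)) abort("Window outside the epoch.",
                       class = "attnpipe_domain_error")
  epochs$data <- epochs$data[, sel, , drop = FALSE]
  epochs$times <- epochs$times[sel]
  epochs
}

#' Tidy a small epoch set into long format
#'
#' One row per channel x time x trial; intended for toy data and
#' plotting, not for full-size sessions.
#'
#' @param x An `epoch_set`.
#' @param ... Unused.
#' @return A tibble with `trial`, `channel`, `time`, `voltage`.
#' @exportS3Method generics::tidy
tidy.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    trial = rep(seq_len(d[3]), each = d[1] * d[2]),
    channel = rep(rep(x$channel_names, d[2]), d[3]),
    time = rep(rep(x$times, each = d[1]), d[3]),
    voltage = as.vector(x$data)
  )
}
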