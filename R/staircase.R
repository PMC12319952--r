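#' Adaptive 2-down-1-up staircase
#'
#' Coherence decreases by `step` after two consecutive correct responses
#' and increases by `step` after every error, converging on the level
#' yielding \eqn{\sqrt{0.5} \approx 70.7\%} correct. Coherence is clamped
#' to `[0.2 + step, 1]`: 0.2 is the pure-noise floor, so the lowest
#' presentable signal level sits one step above it.
#'
#' @param start Starting coherence (default 0.8).
#' @param step Coherence change per update (default 0.04).
#' @return `staircase_new()` returns a `staircase` object;
#'   `staircase_update()` returns the updated object.
#' @examples
#' s <- staircase_new()
#' s <- staircase_update(s, correct = TRUE)
#' @export
staircase_new <- function(start = 0.8, step = 0.04) {
  stopifnot(start > 0.2, start <= 1, step > 0)
  structure(
    list(
      coherence = start, step = step,
      consecutive_correct = 0L, n_trials = 0L, n_reversals = 0L,
      last_direction = 0L, # -1 down, +1 up, 0 none yet
      reversal_levels = numeric(),
      history = tibble(coherence = numeric(), correct = logical())
    ),
    class = "staircase"
  )
}

#' @rdname staircase_new
#' @param state A `staircase` object.
#' @param correct Logical: was the response on this (target) trial correct?
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase"), is.logical(correct),
            length(correct) == 1)
  level <- state$coherence
  state$history <- dplyr::bind_rows(
    state$history, tibble(coherence = level, correct = correct)
  )
  state$n_trials <- state$n_trials + 1L
  direction <- 0L
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 2L) {
      state$coherence <- max(0.2 + state$step, level - state$step)
      state$consecutive_correct <- 0L
      direction <- -1L
    }
  } else {
    state$coherence <- min(1, level + state$step)
    state$consecutive_correct <- 0L
    direction <- 1L
  }
  if (direction != 0L) {
    if (state$last_direction != 0L && direction != state$last_direction) {
      state$n_reversals <- state$n_reversals + 1L
      state$reversal_levels <- c(state$reversal_levels, level)
    }
    state$last_direction <- direction
  }
  state
}

#' Threshold estimate from a finished staircase
#'
#' Mean of the reversal coherence levels; the first two reversals are
#' discarded when at least six occurred, to skip the initial descent.
#' A monotone run without any reversal (e.g. an observer who is always
#' correct, driving the level to the floor) falls back to the final
#' coherence level.
#'
#' @param state A `staircase` object.
#' @return Numeric threshold.
#' @export
staircase_threshold <- function(state) {
  lv <- state$reversal_levels
  if (length(lv) == 0) return(state$coherence)
  if (length(lv) >= 6) lv <- lv[-(1:2)]
  mean(lv)
}

#' Run the interleaved threshold session
#'
#' Seven staircases — one per palette color — interleaved over
#' `n_runs * trials_per_run` trials (5 runs of 84 trials by default, i.e.
#' 60 trials per staircase). 75% of each color's trials present a target
#' at the staircase's current coherence; noise trials (coherence 0.2) do
#' not update the staircase, which tracks signal level only.
#'
#' @param observer A function `p_correct(color, coherence, is_target)`
#'   returning the probability of a correct response; see
#'   [make_threshold_observer()].
#' @param seed Integer seed governing trial order and response sampling.
#' @param n_runs,trials_per_run Session size (defaults 5 and 84).
#' @param start,step Staircase settings.
#' @param palette Color labels, one staircase each.
#' @return A tibble with one row per color: `color`, `threshold`,
#'   `n_trials`, `n_target_trials`, `n_reversals`, `converged` (FALSE when
#'   the staircase pinned at the 1.0 ceiling, mirroring the exclusion of
#'   observers who cannot reach criterion at maximal stimulus strength).
#' @export
run_threshold_session <- function(observer, seed = 1, n_runs = 5,
                                  trials_per_run = 84, start = 0.8,
                                  step = 0.04, palette = color_palette()) {
  n_total <- n_runs * trials_per_run
  stopifnot(n_total %% length(palette) == 0)
  per_color <- n_total / length(palette)
  with_rng(seed, {
    stairs <- setNames(
      lapply(palette, function(...) staircase_new(start, step)), palette
    )
    n_tgt <- round(per_color * 0.75)
    trial_tbl <- tibble(
      color = rep(palette, each = per_color),
      is_target = as.vector(vapply(
        palette,
        function(...) sample(rep(c(TRUE, FALSE), c(n_tgt, per_color - n_tgt))),
        logical(per_color)
      ))
    )
    trial_tbl <- trial_tbl[sample(nrow(trial_tbl)), ]
    pinned <- setNames(logical(length(palette)), palette)
    for (i in seq_len(nrow(trial_tbl))) {
      col <- trial_tbl$color[i]
      tgt <- trial_tbl$is_target[i]
      lev <- if (tgt) stairs[[col]]$coherence else 0.2
      p <- observer(col, lev, tgt)
      if (!is.finite(p) || p < 0 || p > 1) {
        abort("Observer returned a probability outside [0, 1].",
              class = "attnpipe_domain_error")
      }
      correct <- runif(1) < p
      if (tgt) {
        stairs[[col]] <- staircase_update(stairs[[col]], correct)
        if (stairs[[col]]$coherence >= 1) pinned[col] <- TRUE
      }
    }
    tibble(
      color = palette,
      threshold = vapply(stairs, staircase_threshold, numeric(1)),
      n_trials = per_color,
      n_target_trials = n_tgt,
      n_reversals = vapply(stairs, function(s) s$n_reversals, integer(1)),
      converged = !unname(pinned)
    )
  })
}

#' Psychometric observer for the threshold task
#'
#' Cumulative-normal psychometric function over coherence above the 0.2
#' noise floor, parameterized directly by the coherence giving
#' `p_at_threshold` correct (the staircase's 70.7% convergence point by
#' default). On noise trials the observer is correct (responds "noise")
#' with probability `p_noise_correct`.
#'
#' @param threshold Coherence at which performance equals `p_at_threshold`.
#' @param slope SD of the underlying cumulative normal (coherence units).
#' @param p_at_threshold Probability anchored at `threshold`
#'   (default `sqrt(0.5)`).
#' @param lapse Lapse rate mixing toward 50% guessing.
#' @param p_noise_correct Correct-rejection probability on noise trials.
#' @return A function `(color, coherence, is_target) -> probability`.
#' @export
make_threshold_observer <- function(threshold = 0.44, slope = 0.08,
                                    p_at_threshold = sqrt(0.5),
                                    lapse = 0.01, p_noise_correct = 0.8) {
  if (is.null(names(threshold))) {
    thr <- function(color) threshold
  } else {
    thr <- function(color) unname(threshold[color])
  }
  offset <- qnorm(p_at_threshold) * slope
  function(color, coherence, is_target) {
    if (!is_target) return(p_noise_correct)
    p <- stats::pnorm(coherence, mean = thr(color) - offset, sd = slope)
    (1 - lapse) * p + lapse * 0.5
  }
}

#' 70.7%-correct point of an observer's psychometric function
#'
#' Numerical inversion by bisection on the coherence axis; the oracle used
#' in staircase-convergence checks.
#'
#' @param observer A `(color, coherence, is_target)` probability function.
#' @param color Color whose function is inverted.
#' @param p Target probability (default `sqrt(0.5)`).
#' @return Coherence level where the observer's accuracy crosses `p`.
#' @export
psychometric_point <- function(observer, color = "red", p = sqrt(0.5)) {
  f <- function(x) observer(color, x, TRUE) - p
  stats::uniroot(f, c(0.2, 1), tol = 1e-8)$root
}
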