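#' Behavioral observer parameters
#'
#' Signal-detection observer for the coherence detection task. On every
#' trial the decision variable is
#' `evidence = s_eff * (coherence - 0.2) + N(0, internal_noise_sd)` and the
#' observer reports "target" when evidence exceeds `criterion`. Two
#' template models are available:
#'
#' * `"weakened"`: all cued templates are active simultaneously at reduced
#'   strength; `s_eff` is the condition's `template_strength` on every
#'   trial.
#' * `"switching"`: a single template is active at a time; on multi-cue
#'   trials the attended color is drawn uniformly from the cued colors
#'   each trial, and `s_eff` equals the one-cue strength when the attended
#'   color is the trial's present color, else the no-cue strength.
#'
#' Response time decreases with distance of the evidence from the
#' criterion: `rt = (rt_base + rt_gain * exp(-|evidence - criterion|)) *
#' lognormal noise`.
#'
#' @param model `"weakened"` or `"switching"`.
#' @param template_strength Named vector over cue conditions
#'   (`no <= three <= two <= one` sensitivity multipliers).
#' @param internal_noise_sd SD of the evidence noise (evidence units).
#' @param criterion Decision criterion (evidence units).
#' @param rt_base,rt_gain,rt_noise_sd Response-time model: base latency
#'   (s), evidence-dependent gain (s), and lognormal noise SD.
#' @return An `observer_params` list.
#' @export
observer_params <- function(model = c("weakened", "switching"),
                            template_strength = c(no = 1.2, one = 6,
                                                  two = 4.5, three = 1.2),
                            internal_noise_sd = 1, criterion = 0.25,
                            rt_base = 0.35, rt_gain = 0.45,
                            rt_noise_sd = 0.15) {
  model <- match.arg(model)
  s <- template_strength
  stopifnot(all(s >= 0),
            s["one"] >= s["two"], s["two"] >= s["three"],
            s["three"] >= s["no"])
  structure(
    list(model = model, template_strength = s,
         internal_noise_sd = internal_noise_sd, criterion = criterion,
         rt_base = rt_base, rt_gain = rt_gain, rt_noise_sd = rt_noise_sd),
    class = "observer_params"
  )
}

#' Simulate behavioral responses to a trial schedule
#'
#' @param schedule A `trial_schedule` tibble.
#' @param obs An [observer_params()] list.
#' @param seed Integer seed; responses are a pure function of
#'   `(schedule, obs, seed)`.
#' @return The schedule with added columns `evidence`, `response`
#'   (`"target"`/`"noise"`), `correct`, `rt` (seconds).
#' @export
simulate_observer <- function(schedule, obs = observer_params(), seed = 1) {
  stopifnot(inherits(obs, "observer_params"))
  n <- nrow(schedule)
  s <- obs$template_strength
  with_rng(seed, {
    s_eff <- numeric(n)
    for (i in seq_len(n)) {
      cond <- schedule$cue_condition[i]
      cued <- schedule$cued_colors[[i]]
      if (obs$model == "weakened" || length(cued) <= 1) {
        s_eff[i] <- unname(s[cond])
        if (obs$model == "switching" && length(cued) == 1) {
          s_eff[i] <- unname(s["one"])
        }
      } else {
        attended <- sample(cued, 1)
        s_eff[i] <- if (attended == schedule$target_color[i]) {
          unname(s["one"])
        } else {
          unname(s["no"])
        }
      }
    }
    evidence <- s_eff * (schedule$coherence - 0.2) +
      rnorm(n, sd = obs$internal_noise_sd)
    yes <- evidence > obs$criterion
    rt <- (obs$rt_base + obs$rt_gain * exp(-abs(evidence - obs$criterion))) *
      exp(rnorm(n, sd = obs$rt_noise_sd))
    schedule |>
      dplyr::mutate(
        evidence = evidence,
        response = ifelse(yes, "target", "noise"),
        correct = yes == .data$is_target,
        rt = rt
      )
  })
}

#' Summarize behavioral performance per cue condition
#'
#' Hit rate, false-alarm rate, median RTs of hits and correct rejections,
#' and signal-detection measures (log-linear corrected d-prime and
#' criterion) per cue condition.
#'
#' @param responses Output of [simulate_observer()] (or any tibble with
#'   `cue_condition`, `is_target`, `response`, `rt`).
#' @return A tibble, one row per cue condition.
#' @export
summarize_behavior <- function(responses) {
  responses |>
    dplyr::group_by(.data$cue_condition) |>
    dplyr::summarize(
      n_trials = dplyr::n(),
      hit_rate = mean(.data$response[.data$is_target] == "target"),
      fa_rate = mean(.data$response[!.data$is_target] == "target"),
      hit_rt = median(.data$rt[.data$is_target &
                                 .data$response == "target"]),
      cr_rt = median(.data$rt[!.data$is_target &
                                .data$response == "noise"]),
      dprime = sdt_measures(
        sum(.data$is_target & .data$response == "target"),
        sum(.data$is_target & .data$response == "noise"),
        sum(!.data$is_target & .data$response == "target"),
        sum(!.data$is_target & .data$response == "noise")
      )$dprime,
      criterion = sdt_measures(
        sum(.data$is_target & .data$response == "target"),
        sum(.data$is_target & .data$response == "noise"),
        sum(!.data$is_target & .data$response == "target"),
        sum(!.data$is_target & .data$response == "noise")
      )$criterion,
      .groups = "drop"
    )
}
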