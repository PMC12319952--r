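#' Pipeline configuration
#'
#' A run of the full pipeline is a pure function of its configuration.
#' Two profiles are provided: `"desk"` — a scaled-down configuration for
#' routine reruns (12 subjects, 10 target trials per color per condition,
#' 500 permutations, 2 cross-validation iterations, 19-channel posterior
#' montage, reduced wavelet bank) — and `"full"` — the complete design
#' (28 subjects, 45 target + 15 noise trials per color per condition, the
#' 64-channel cap, 10,000 permutations, 10 iterations, 60 wavelets).
#'
#' @param profile `"desk"` or `"full"`.
#' @param ... Named overrides of top-level fields (e.g.
#'   `n_subjects = 6`), or of nested blocks by supplying the whole block
#'   (e.g. `stats = list(n_perm = 200, alpha = 0.05)`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    n_subjects = if (profile == "desk") 12 else 28,
    seed = 1,
    montage = if (profile == "desk") "posterior19" else "full64",
    schedule = list(
      n_target_per_color = if (profile == "desk") 10 else 45,
      n_noise_per_color = 5 * (if (profile == "desk") 1 else 3),
      n_blocks = 10,
      coherence = 0.45
    ),
    generator = list(),
    observer = list(),
    variability = list(gain_sd = 0, behavior_coupling = 0),
    preprocessing = list(threshold = 200, band = c(0.01, 80), notch = 60),
    decoding = list(
      k = 5,
      iterations = if (profile == "desk") 2 else 10,
      rate = 100, lowpass = 15, smooth_fwhm = 0.02, smooth_window = 0.04
    ),
    tfr = list(
      n_wavelets = if (profile == "desk") 20 else 60,
      fmin = 2, fmax = if (profile == "desk") 30 else 80, cycles = 5
    ),
    bands = list(alpha = c(8, 14)),
    stats = list(n_perm = if (profile == "desk") 500 else 10000,
                 alpha = 0.05),
    windows = list(prep = c(0.5, 1.25), post_cue = c(0, 1),
                   post_target = c(0, 1)),
    run_tfr = TRUE,
    out_dir = NULL
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  structure(base, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()] list.
#' @return Character vector of issues; empty when valid.
#' @export
validate_config <- function(config) {
  issues <- character()
  add <- function(msg) issues <<- c(issues, msg)
  ch <- tryCatch(resolve_montage(config$montage), error = function(e) NULL)
  if (is.null(ch)) {
    add(sprintf("montage: unknown montage '%s'", config$montage))
  } else {
    if (!all(c("TP9", "TP10") %in% ch)) {
      add("montage: missing reference channels TP9/TP10")
    }
    if (!all(posterior_17 %in% ch)) {
      add("montage: missing posterior electrodes")
    }
  }
  if (is.null(config$seed)) add("seed: missing master seed")
  if (!is.numeric(config$n_subjects) || config$n_subjects < 1) {
    add("n_subjects: must be a positive integer")
  }
  alpha_band <- config$bands$alpha
  if (is.null(alpha_band) || length(alpha_band) != 2 ||
      alpha_band[2] <= alpha_band[1]) {
    add("bands.alpha: must be an increasing 2-element band")
  }
  if (!is.null(alpha_band) && length(alpha_band) == 2 &&
      !is.null(config$tfr$fmax) && alpha_band[2] > config$tfr$fmax) {
    add("bands.alpha: exceeds the wavelet bank range tfr.fmax")
  }
  coh <- config$schedule$coherence
  if (any(coh < 0.2 | coh > 1)) {
    add("schedule.coherence: outside [0.2, 1]")
  }
  if (config$decoding$k > config$schedule$n_target_per_color) {
    add("decoding.k: more folds than target trials per color")
  }
  g <- config$generator$evoked_gain %||%
    formals(generator_params)$evoked_gain |> eval()
  if (!is.null(g) && !all(g >= 0)) add("generator.evoked_gain: negative gain")
  if (config$preprocessing$threshold <= 0) {
    add("preprocessing.threshold: must be positive microvolts")
  }
  if (config$stats$n_perm < 1) add("stats.n_perm: must be >= 1")
  issues
}

subject_generator <- function(config, subject, dgain = 0) {
  gen_args <- config$generator
  gen_args$channels <- resolve_montage(config$montage)
  gen_args$subject_seed <- child_seed(config$seed, subject, 7)
  g <- gen_args$evoked_gain %||% eval(formals(generator_params)$evoked_gain)
  g["one"] <- max(0, g["one"] + dgain)
  gen_args$evoked_gain <- g
  do.call(generator_params, gen_args)
}

subject_observer <- function(config, dgain = 0) {
  obs_args <- config$observer
  s <- obs_args$template_strength %||%
    eval(formals(observer_params)$template_strength)
  s["one"] <- max(s["two"],
                  s["one"] + config$variability$behavior_coupling * dgain)
  obs_args$template_strength <- s
  do.call(observer_params, obs_args)
}

run_subject <- function(config, subject) {
  dgain <- if (config$variability$gain_sd > 0) {
    with_rng(child_seed(config$seed, subject, 11),
             rnorm(1, sd = config$variability$gain_sd))
  } else 0
  gen <- subject_generator(config, subject, dgain)
  obs <- subject_observer(config, dgain)
  sched <- build_eeg_schedule(
    seed = child_seed(config$seed, subject, 1),
    coherence = config$schedule$coherence,
    n_target_per_color = config$schedule$n_target_per_color,
    n_noise_per_color = config$schedule$n_noise_per_color,
    n_blocks = config$schedule$n_blocks
  )
  responses <- simulate_observer(sched, obs,
                                 seed = child_seed(config$seed, subject, 2))
  record <- simulate_session(sched, gen,
                             seed = child_seed(config$seed, subject, 3))
  pp <- config$preprocessing
  record <- rereference(record)
  record <- filter_continuous(record, pp$band, pp$notch)
  ep_cue <- reject_artifacts(epoch_and_baseline(record, "cue"),
                             pp$threshold, c(-0.5, 2))
  ep_tgt0 <- epoch_and_baseline(record, "target")
  ep_tgt <- reject_artifacts(ep_tgt0, pp$threshold, range(ep_tgt0$times))
  list(schedule = sched, responses = responses, epochs_cue = ep_cue,
       epochs_target = ep_tgt, dgain = dgain,
       rejection = c(cue = attr(ep_cue, "rejection_fraction"),
                     target = attr(ep_tgt, "rejection_fraction")))
}

decode_subject <- function(config, sub, seed_off) {
  dec <- config$decoding
  run_dec <- function(epochs, lock, two_cue, cond, seed) {
    prep <- prepare_for_decoding(epochs, rate = dec$rate,
                                 lowpass = dec$lowpass,
                                 smooth_fwhm = dec$smooth_fwhm)
    res <- if (two_cue) {
      decode_two_cue_colors(prep, k = dec$k, iterations = dec$iterations,
                            seed = seed)
    } else {
      temporal_decode(prep, k = dec$k, iterations = dec$iterations,
                      seed = seed)
    }
    smooth_accuracy(res, dec$smooth_window) |>
      dplyr::mutate(lock = lock, condition = cond, .before = 1)
  }
  keep_cond <- function(ep, cond) {
    select_trials(ep, ep$trial_meta$is_target &
                    ep$trial_meta$cue_condition == cond)
  }
  dplyr::bind_rows(
    run_dec(keep_cond(sub$epochs_cue, "one"), "cue", FALSE, "one",
            child_seed(seed_off, 1)),
    run_dec(keep_cond(sub$epochs_cue, "two"), "cue", TRUE, "two",
            child_seed(seed_off, 2)),
    run_dec(keep_cond(sub$epochs_target, "one"), "target", FALSE, "one",
            child_seed(seed_off, 3)),
    run_dec(keep_cond(sub$epochs_target, "two"), "target", FALSE, "two",
            child_seed(seed_off, 4))
  )
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates `n_subjects` sessions (EEG + behavior) and carries out the
#' complete analysis: preprocessing, behavioral summary and tests,
#' posterior ERPs and alpha power with paired cluster tests, cue-locked
#' and target-locked color decoding with vs-chance and paired cluster
#' tests, and the brain-behavior correlation. Deterministic under a
#' fixed config seed.
#'
#' @param config A [pipeline_config()] list.
#' @return An `attnpipe_report` list of tibbles and test objects; when
#'   `config$out_dir` is set, TSV/JSON twins of every table are written
#'   there.
#' @export
run_full_pipeline <- function(config = pipeline_config("desk")) {
  issues <- validate_config(config)
  if (length(issues) > 0) {
    abort(paste0("Invalid config:\n", paste("-", issues, collapse = "\n")),
          class = "attnpipe_config_error")
  }
  t0 <- Sys.time()
  n_sub <- config$n_subjects
  timings <- list()

  subjects <- vector("list", n_sub)
  behavior <- vector("list", n_sub)
  erp_rows <- list()
  alpha_rows <- list()
  dec_rows <- vector("list", n_sub)
  rejection <- matrix(NA_real_, n_sub, 2,
                      dimnames = list(NULL, c("cue", "target")))
  dgains <- numeric(n_sub)

  for (s in seq_len(n_sub)) {
    sub <- run_subject(config, s)
    dgains[s] <- sub$dgain
    rejection[s, ] <- sub$rejection

    # behavior restricted to trials surviving target-locked cleaning
    kept <- sub$epochs_target$trial_meta$trial
    resp <- sub$responses[sub$responses$trial %in% kept, ]
    behavior[[s]] <- summarize_behavior(resp) |>
      dplyr::mutate(subject = s, .before = 1)

    for (lk in c("cue", "target")) {
      ep <- if (lk == "cue") sub$epochs_cue else sub$epochs_target
      erp_rows[[paste(s, lk)]] <- compute_erp(ep) |>
        dplyr::mutate(subject = s, lock = lk, .before = 1)
    }
    if (isTRUE(config$run_tfr)) {
      bank <- gabor_bank(config$tfr$n_wavelets, config$tfr$fmin,
                         config$tfr$fmax, config$tfr$cycles)
      ep_post <- select_channels(
        select_trials(sub$epochs_cue, sub$epochs_cue$trial_meta$is_target),
        posterior_17
      )
      tfr <- baseline_db(gabor_tfr(ep_post, bank))
      alpha_rows[[s]] <- band_power(tfr, config$bands$alpha) |>
        dplyr::mutate(subject = s, .before = 1)
    }
    dec_rows[[s]] <- decode_subject(config, sub,
                                    child_seed(config$seed, s, 23)) |>
      dplyr::mutate(subject = s, .before = 1)
    subjects[[s]] <- list(responses = resp)
  }
  timings$simulation_and_subject_level <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))

  behavior <- dplyr::bind_rows(behavior)
  erp <- dplyr::bind_rows(erp_rows)
  alpha <- dplyr::bind_rows(alpha_rows)
  decoding <- dplyr::bind_rows(dec_rows)

  # ---- group-level inference -------------------------------------------
  t1 <- Sys.time()
  ns <- config$stats
  wide <- function(df, val) {
    m <- df |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "time",
                         values_from = dplyr::all_of(val)) |>
      dplyr::arrange(.data$subject)
    as.matrix(m[, -1])
  }
  tests <- list()
  for (lk in c("cue", "target")) {
    sub_erp <- erp[erp$lock == lk, ]
    a <- wide(sub_erp[sub_erp$condition == "one", ], "amplitude")
    b <- wide(sub_erp[sub_erp$condition == "two", ], "amplitude")
    times <- sort(unique(sub_erp$time))
    tests[[paste0("erp_", lk, "_one_vs_two")]] <-
      cluster_permutation_paired(a, b, times, ns$n_perm, ns$alpha,
                                 seed = child_seed(config$seed, 31))
  }
  if (nrow(alpha) > 0) {
    a <- wide(alpha[alpha$condition == "one", ], "power_db")
    b <- wide(alpha[alpha$condition == "two", ], "power_db")
    times <- sort(unique(alpha$time))
    tests$alpha_one_vs_two <-
      cluster_permutation_paired(a, b, times, ns$n_perm, ns$alpha,
                                 seed = child_seed(config$seed, 32))
  }
  for (lk in c("cue", "target")) {
    dl <- decoding[decoding$lock == lk, ]
    times <- sort(unique(dl$time))
    win <- if (lk == "cue") config$windows$post_cue else
      config$windows$post_target
    sel <- times >= win[1] & times <= win[2]
    mats <- lapply(c("one", "two"), function(cc) {
      wide(dl[dl$condition == cc, ], "accuracy")[, sel, drop = FALSE]
    })
    tests[[paste0("decoding_", lk, "_one_vs_chance")]] <-
      cluster_permutation_vs_chance(mats[[1]], 1 / 7, times[sel],
                                    ns$n_perm, ns$alpha,
                                    seed = child_seed(config$seed, 33))
    tests[[paste0("decoding_", lk, "_two_vs_chance")]] <-
      cluster_permutation_vs_chance(mats[[2]], 1 / 7, times[sel],
                                    ns$n_perm, ns$alpha,
                                    seed = child_seed(config$seed, 34))
    tests[[paste0("decoding_", lk, "_one_vs_two")]] <-
      cluster_permutation_paired(mats[[1]], mats[[2]], times[sel],
                                 ns$n_perm, ns$alpha,
                                 seed = child_seed(config$seed, 35))
  }

  bw <- behavior |>
    tidyr::pivot_wider(id_cols = "subject", names_from = "cue_condition",
                       values_from = c("hit_rate", "fa_rate", "hit_rt",
                                       "cr_rt", "dprime"))
  behavior_tests <- tibble(
    measure = c("hit_rate", "fa_rate", "hit_rt", "cr_rt", "dprime"),
    test = purrr::map(.data$measure, function(m) {
      paired_t(bw[[paste0(m, "_one")]], bw[[paste0(m, "_two")]])
    })
  ) |>
    dplyr::mutate(purrr::map_dfr(.data$test, tidy)) |>
    dplyr::select(-"test")

  # ---- brain-behavior correlation --------------------------------------
  med_rt <- dplyr::bind_rows(purrr::imap(subjects, function(sb, s) {
    sb$responses |>
      dplyr::filter(.data$is_target, .data$response == "target") |>
      dplyr::group_by(.data$cue_condition) |>
      dplyr::summarize(med_rt = median(.data$rt), .groups = "drop") |>
      dplyr::mutate(subject = s)
  }))
  stim_effect <- vapply(seq_len(n_sub), function(s) {
    eff <- vapply(c("one", "two"), function(cc) {
      rtv <- med_rt$med_rt[med_rt$subject == s & med_rt$cue_condition == cc]
      dl <- decoding[decoding$subject == s & decoding$lock == "target" &
                       decoding$condition == cc, ]
      window_mean(dl, c(0, rtv))
    }, numeric(1))
    eff["one"] - eff["two"]
  }, numeric(1))
  prep_effect <- vapply(seq_len(n_sub), function(s) {
    eff <- vapply(c("one", "two"), function(cc) {
      dl <- decoding[decoding$subject == s & decoding$lock == "cue" &
                       decoding$condition == cc, ]
      window_mean(dl, config$windows$prep)
    }, numeric(1))
    eff["one"] - eff["two"]
  }, numeric(1))
  hit_effect <- bw$hit_rate_one - bw$hit_rate_two
  brain_behavior <- dplyr::bind_rows(
    brain_behavior_correlation(hit_effect, stim_effect) |>
      dplyr::mutate(window = "stimulus", .before = 1),
    brain_behavior_correlation(hit_effect, prep_effect) |>
      dplyr::mutate(window = "preparation", .before = 1)
  )
  timings$group_level <- as.numeric(difftime(Sys.time(), t1, units = "secs"))

  report <- structure(
    list(behavior = behavior, behavior_tests = behavior_tests,
         erp = erp, alpha = alpha, decoding = decoding,
         cluster_tests = tests, brain_behavior = brain_behavior,
         effects = tibble(subject = seq_len(n_sub), dgain = dgains,
                          hit_effect = hit_effect,
                          stim_decoding_effect = stim_effect,
                          prep_decoding_effect = prep_effect),
         rejection = as_tibble(rejection) |>
           dplyr::mutate(subject = seq_len(n_sub), .before = 1),
         config = config, timings = timings),
    class = "attnpipe_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.attnpipe_report <- function(x, ...) {
  cat(sprintf("<attnpipe_report> %d subjects, profile '%s'\n",
              x$config$n_subjects, x$config$profile))
  cat("Behavioral tests (one-cue vs two-cue):\n")
  print(as.data.frame(x$behavior_tests), row.names = FALSE, digits = 3)
  cat("Cluster tests:\n")
  for (nm in names(x$cluster_tests)) {
    sig <- significant_clusters(x$cluster_tests[[nm]])
    cat(sprintf("  %-32s %d significant cluster(s)\n", nm, nrow(sig)))
  }
  cat("Brain-behavior correlation:\n")
  print(as.data.frame(x$brain_behavior), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a pipeline report to TSV/JSON files
#'
#' @param report An `attnpipe_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wtsv(report$behavior, "behavior")
  wtsv(report$behavior_tests, "behavior_tests")
  wtsv(report$erp, "erp")
  if (nrow(report$alpha) > 0) wtsv(report$alpha, "alpha_power")
  wtsv(report$decoding, "decoding")
  wtsv(report$brain_behavior, "brain_behavior")
  wtsv(dplyr::bind_rows(purrr::imap(report$cluster_tests, function(ct, nm) {
    dplyr::mutate(tidy(ct), test = nm, .before = 1)
  })), "cluster_tests")
  summary_json <- list(
    profile = report$config$profile,
    n_subjects = report$config$n_subjects,
    seed = report$config$seed,
    timings = report$timings,
    rejection_fraction = colMeans(report$rejection[, c("cue", "target")]),
    significant_clusters = purrr::map_int(
      report$cluster_tests, function(ct) nrow(significant_clusters(ct))
    ),
    brain_behavior = as.list(setNames(report$brain_behavior$r,
                                      report$brain_behavior$window))
  )
  jsonlite::write_json(summary_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
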