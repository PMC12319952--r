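#' Compose one random-dot color field
#'
#' A display contains `n_dots` dots in five colors. A *noise* field carries
#' every color in equal proportion (0.2). A *target* field over-represents
#' one color: with coherence \eqn{P_t}, each of the four non-target colors
#' appears with proportion \eqn{P_n = (1 - P_t)/4}, so that
#' \eqn{P_t = 1 - 4 P_n}. Coherence 0.2 is therefore the noise floor.
#'
#' Fractional ideal counts are resolved by flooring and assigning the
#' remaining dots by largest fractional part (target color first on ties),
#' so counts always sum exactly to `n_dots`.
#'
#' @param target_color Over-represented color label (must be in
#'   `display_colors`).
#' @param coherence Proportion of target-colored dots, in `[0.2, 1]`.
#' @param display_colors Character vector of exactly 5 distinct colors.
#' @param n_dots Total dots in the field (default 240).
#' @param is_target Logical; `FALSE` composes the noise field (all equal),
#'   defaulting from `coherence <= 0.2`.
#' @return A `dot_field` tibble with one row per display color: `color`,
#'   `count`, `proportion`, `is_target_color`; attributes `n_dots`,
#'   `coherence`, `is_target`, `target_color`.
#' @examples
#' compose_dot_field("red", 0.6, c("red", "green", "blue", "yellow", "pink"))
#' @export
compose_dot_field <- function(target_color, coherence, display_colors,
                              n_dots = 240, is_target = coherence > 0.2) {
  if (!is.numeric(coherence) || length(coherence) != 1 ||
      coherence < 0.2 - 1e-12 || coherence > 1 + 1e-12) {
    abort("`coherence` must be a single value in [0.2, 1].",
          class = "attnpipe_domain_error")
  }
  display_colors <- as.character(display_colors)
  if (length(display_colors) != 5 || anyDuplicated(display_colors)) {
    abort("`display_colors` must hold exactly 5 distinct colors.",
          class = "attnpipe_constraint_error")
  }
  if (!target_color %in% display_colors) {
    abort("`target_color` must be one of `display_colors`.",
          class = "attnpipe_constraint_error")
  }
  if (n_dots < 5) abort("`n_dots` must be at least 5.",
                        class = "attnpipe_domain_error")
  if (!is_target) coherence <- 0.2
  p_t <- coherence
  p_n <- (1 - p_t) / 4
  is_tgt_col <- display_colors == target_color
  props <- ifelse(is_tgt_col, p_t, p_n)
  ideal <- props * n_dots
  counts <- floor(ideal + 1e-9)
  rem <- n_dots - sum(counts)
  if (rem > 0) {
    frac <- ideal - counts
    # largest fractional part wins; target color breaks ties, then order
    ord <- order(-frac, !is_tgt_col, seq_along(frac))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  out <- tibble(
    color = display_colors,
    count = as.integer(counts),
    proportion = as.integer(counts) / n_dots,
    is_target_color = is_tgt_col & is_target
  )
  structure(out,
    n_dots = as.integer(n_dots), coherence = p_t,
    is_target = is_target, target_color = target_color,
    class = c("dot_field", class(out))
  )
}

#' Select the five display colors for a trial
#'
#' The target color is always shown; the other four display colors are
#' drawn without replacement from the palette excluding *all* cued colors,
#' so a cued-but-non-target color never appears in the display.
#'
#' @param target_color The trial's designated color (present in both target
#'   and noise fields).
#' @param cued_colors Character vector of 0-3 cued colors; must contain
#'   `target_color` unless empty (no-cue trials).
#' @param palette The 7-color pool.
#' @param seed Optional integer; when supplied the draw is a pure function
#'   of it, otherwise the ambient RNG stream is used.
#' @return Character vector of 5 display colors, target color first.
#' @export
select_display_colors <- function(target_color, cued_colors = character(),
                                  palette = color_palette(), seed = NULL) {
  cued_colors <- as.character(cued_colors)
  if (length(cued_colors) > 0 && !target_color %in% cued_colors) {
    abort("`target_color` must be among `cued_colors` on cued trials.",
          class = "attnpipe_constraint_error")
  }
  pool <- setdiff(palette, union(cued_colors, target_color))
  if (length(pool) < 4) {
    abort("Fewer than 4 colors remain after excluding cued colors.",
          class = "attnpipe_infeasible_error")
  }
  draw <- function() c(target_color, sample(pool, 4))
  if (is.null(seed)) draw() else with_rng(seed, draw())
}

cue_angles <- function(n_cues) {
  if (n_cues == 0) return(numeric())
  rot <- runif(1, 0, 360)
  (rot + (seq_len(n_cues) - 1) * 360 / n_cues) %% 360
}

# One block's worth of trials for a given cue condition. Runs inside the
# schedule builder's seeded RNG scope.
build_block <- function(block_index, cue_condition, n_trials, p_target,
                        jitter_range, coherence, palette,
                        colors = NULL) {
  n_cues <- match(cue_condition, c("no", "one", "two", "three")) - 1L
  n_target <- round(n_trials * p_target)
  tgt_flags <- sample(rep(c(TRUE, FALSE), c(n_target, n_trials - n_target)))
  if (is.null(colors)) {
    colors <- sample(palette, n_trials, replace = TRUE)
  } else {
    colors <- sample(colors) # balanced set supplied by the caller
  }
  coh <- function(color) {
    if (length(coherence) == 1 && is.null(names(coherence))) coherence
    else unname(coherence[color])
  }
  rows <- purrr::map(seq_len(n_trials), function(i) {
    tcol <- colors[i]
    cued <- if (n_cues == 0) character() else {
      c(tcol, sample(setdiff(palette, tcol), n_cues - 1L))
    }
    disp <- select_display_colors(tcol, cued, palette)
    tibble(
      block = block_index,
      cue_condition = cue_condition,
      cued_colors = list(cued),
      target_color = tcol,
      is_target = tgt_flags[i],
      coherence = if (tgt_flags[i]) coh(tcol) else 0.2,
      display_colors = list(disp),
      cue_to_stim_interval = if (diff(jitter_range) == 0) jitter_range[1]
                             else runif(1, jitter_range[1], jitter_range[2]),
      cue_positions = list(cue_angles(n_cues))
    )
  })
  dplyr::bind_rows(rows)
}

finalize_schedule <- function(blocks, session, iti = 2.0,
                              cue_duration = 0.5, stim_duration = 0.15) {
  sched <- dplyr::bind_rows(blocks)
  dur <- cue_duration + sched$cue_to_stim_interval + stim_duration + iti
  sched <- sched |>
    dplyr::mutate(
      trial = dplyr::row_number(),
      onset = cumsum(dplyr::lag(dur, default = 0)) + iti,
      stim_onset = .data$onset + cue_duration + .data$cue_to_stim_interval,
      .before = 1
    )
  structure(sched, session = session,
            class = c("trial_schedule", class(sched)))
}

#' Build the practice-session trial schedule
#'
#' Eight 84-trial blocks arranged as two superblocks, each a random order
#' of the four cue conditions (no/one/two/three cues); within every block
#' 75% target and 25% noise trials; cue-to-stimulus interval fixed at
#' 0.8 s. This yields 168 trials per cue condition (126 target + 42 noise)
#' and 672 trials in total.
#'
#' @param seed Integer seed; the schedule is a pure function of it.
#' @param coherence Target coherence level(s): a scalar or a vector named
#'   by color (e.g. per-color staircase thresholds). Noise trials are
#'   always at the 0.2 floor.
#' @param palette The 7-color pool.
#' @return A `trial_schedule` tibble, one row per trial.
#' @export
build_practice_schedule <- function(seed = 1, coherence = 0.45,
                                    palette = color_palette()) {
  with_rng(seed, {
    conditions <- c(
      sample(c("no", "one", "two", "three")),
      sample(c("no", "one", "two", "three"))
    )
    blocks <- purrr::imap(conditions, function(cond, b) {
      build_block(b, cond, n_trials = 84, p_target = 0.75,
                  jitter_range = c(0.8, 0.8), coherence = coherence,
                  palette = palette)
    })
    finalize_schedule(blocks, session = "practice")
  })
}

#' Build the EEG-session trial schedule
#'
#' Ten 84-trial blocks alternating between the one-cue and two-cue
#' conditions (starting condition randomized). Each condition delivers,
#' per color, exactly 45 target and 15 noise trials — 315 target and 105
#' noise trials per condition, 840 trials in total. The cue-to-stimulus
#' interval is jittered uniformly in `[0.8, 1.1]` s.
#'
#' @inheritParams build_practice_schedule
#' @param n_target_per_color,n_noise_per_color Per-condition trial counts
#'   per color (defaults 45 and 15, the full design).
#' @param n_blocks Total number of alternating blocks (default 10); both
#'   per-color counts must divide evenly over a condition's
#'   `n_blocks / 2` blocks.
#' @param conditions The two alternating cue conditions.
#' @param iti Inter-trial interval in seconds used for onset bookkeeping.
#' @return A `trial_schedule` tibble, one row per trial.
#' @export
build_eeg_schedule <- function(seed = 1, coherence = 0.45,
                               n_target_per_color = 45,
                               n_noise_per_color = 15,
                               n_blocks = 10,
                               conditions = c("one", "two"),
                               iti = 2.0,
                               palette = color_palette()) {
  bpc <- n_blocks / length(conditions) # blocks per condition
  n_col <- length(palette)
  stopifnot(n_blocks %% length(conditions) == 0,
            (n_target_per_color * n_col) %% bpc == 0,
            (n_noise_per_color * n_col) %% bpc == 0)
  tgt_blk <- n_target_per_color * n_col / bpc
  noi_blk <- n_noise_per_color * n_col / bpc
  with_rng(seed, {
    cond_seq <- rep(sample(conditions), n_blocks / length(conditions))
    # per condition: fixed per-color counts, dealt into the condition's
    # blocks so every block keeps the target/noise split
    deal <- function() {
      tgt <- sample(rep(palette, each = n_target_per_color))
      noi <- sample(rep(palette, each = n_noise_per_color))
      purrr::map(seq_len(bpc), function(b) {
        list(colors = c(tgt[(b - 1) * tgt_blk + seq_len(tgt_blk)],
                        noi[(b - 1) * noi_blk + seq_len(noi_blk)]),
             is_target = rep(c(TRUE, FALSE), c(tgt_blk, noi_blk)))
      })
    }
    per_cond <- lapply(setNames(conditions, conditions),
                       function(...) deal())
    # separate counterbalancers for noise and target trials, so the
    # non-target cue marginal is balanced within the target trials that
    # feed the decoding analyses
    pickers <- lapply(setNames(conditions, conditions), function(cond) {
      nc <- match(cond, c("no", "one", "two", "three")) - 1L
      list(make_cue_picker(nc, palette), make_cue_picker(nc, palette))
    })
    counter <- setNames(integer(length(conditions)), conditions)
    blocks <- purrr::imap(cond_seq, function(cond, b) {
      counter[cond] <<- counter[cond] + 1L
      slot <- per_cond[[cond]][[counter[cond]]]
      ord <- sample(length(slot$colors))
      build_block_fixed(
        b, cond, colors = slot$colors[ord], tgt_flags = slot$is_target[ord],
        jitter_range = c(0.8, 1.1), coherence = coherence, palette = palette,
        pick_cues = pickers[[cond]]
      )
    })
    sched <- finalize_schedule(blocks, session = "eeg", iti = iti)
    sched$coherence <- ifelse(sched$is_target,
                              coh_lookup(coherence, sched$target_color), 0.2)
    sched
  })
}

coh_lookup <- function(coherence, colors) {
  if (length(coherence) == 1 && is.null(names(coherence))) {
    rep(coherence, length(colors))
  } else {
    unname(coherence[colors])
  }
}

# Greedy counterbalancer for the additional (non-target) cue colors: each
# pick takes the least-used eligible color so the non-target-cue marginal
# stays near-uniform, which keeps stratified folds feasible when decoding
# the non-target cue color.
make_cue_picker <- function(n_cues, palette) {
  tally <- setNames(numeric(length(palette)), palette)
  function(tcol) {
    if (n_cues == 0L) return(character())
    cued <- tcol
    while (length(cued) < n_cues) {
      pool <- setdiff(palette, cued)
      least <- pool[tally[pool] == min(tally[pool])]
      pick <- if (length(least) == 1) least else sample(least, 1)
      tally[pick] <<- tally[pick] + 1
      cued <- c(cued, pick)
    }
    cued
  }
}

# Variant of build_block with caller-fixed color/target assignment.
build_block_fixed <- function(block_index, cue_condition, colors, tgt_flags,
                              jitter_range, coherence, palette,
                              pick_cues = NULL) {
  n_cues <- match(cue_condition, c("no", "one", "two", "three")) - 1L
  rows <- purrr::map(seq_along(colors), function(i) {
    tcol <- colors[i]
    cued <- if (!is.null(pick_cues)) pick_cues[[tgt_flags[i] + 1L]](tcol)
    else if (n_cues == 0) character() else {
      c(tcol, sample(setdiff(palette, tcol), n_cues - 1L))
    }
    disp <- select_display_colors(tcol, cued, palette)
    tibble(
      block = block_index,
      cue_condition = cue_condition,
      cued_colors = list(cued),
      target_color = tcol,
      is_target = tgt_flags[i],
      coherence = NA_real_,
      display_colors = list(disp),
      cue_to_stim_interval = runif(1, jitter_range[1], jitter_range[2]),
      cue_positions = list(cue_angles(n_cues))
    )
  })
  dplyr::bind_rows(rows)
}

#' Write / read a trial schedule as a BIDS-events-like TSV
#'
#' Set-valued columns (`cued_colors`, `display_colors`, `cue_positions`)
#' are serialized comma-joined; `read_schedule()` restores them to list
#' columns.
#'
#' @param schedule A `trial_schedule` tibble.
#' @param path File path ending in `.tsv`.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `trial_schedule` tibble.
#' @export
write_schedule <- function(schedule, path) {
  flat <- schedule |>
    dplyr::mutate(
      cued_colors = purrr::map_chr(.data$cued_colors, paste, collapse = ","),
      display_colors = purrr::map_chr(.data$display_colors, paste,
                                      collapse = ","),
      cue_positions = purrr::map_chr(
        .data$cue_positions, function(x) paste(format(x, digits = 10),
                                               collapse = ",")
      )
    )
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  flat <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  split_chr <- function(x) strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)
  sched <- flat |>
    dplyr::mutate(
      cued_colors = split_chr(as.character(.data$cued_colors)),
      display_colors = split_chr(as.character(.data$display_colors)),
      cue_positions = purrr::map(split_chr(as.character(.data$cue_positions)),
                                 as.numeric)
    )
  structure(sched, class = c("trial_schedule", class(sched)))
}
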