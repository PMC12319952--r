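# attnpipe

Behavioral and EEG-decoding analysis of feature-based attention to
color, as a tested, fully reproducible R pipeline.

## The problem

How many color *attentional templates* can an observer keep active at
once? In the underlying paradigm, observers detect a weak
color-coherence signal — an over-representation of one color in a
240-dot five-color field — after being cued with one to three possible
target colors (or none). Coherence is defined by

> Coherence = P_t = 1 − 4·P_n

where P_t is the proportion of the over-represented color and P_n the
proportion of each of the four other colors; P_t = 0.2 is pure noise.
If maintaining several templates carries a cost, detection performance
and the strength of the attended color's neural representation — read
out from posterior EEG with a per-timepoint multiclass LDA (chance =
1/7) — should both fall as the number of cued colors grows, and the two
effects should correlate across observers.

attnpipe implements every stage as composable, seeded functions:

* **Task design** — dot-field composition, cued trial schedules
  (practice: 8 × 84 trials over four cue conditions; EEG session:
  10 alternating one-/two-cue blocks, 45 target + 15 noise trials per
  color per condition), interleaved 2-down-1-up staircases converging
  at 70.7% correct.
* **Synthetic data** — a generative model of 64-channel scalp EEG (1/f
  background, posterior alpha with event-related suppression,
  subject-specific color topographies scaled by condition-dependent
  attentional gain) and a signal-detection behavioral observer with
  weakened-template and single-template-switching variants.
* **Preprocessing** — TP9/TP10 re-referencing, zero-phase Butterworth
  band-pass (0.01–80 Hz half-amplitude) + 60 Hz notch, cue-/target-
  locked epoching with baseline subtraction, 200 µV threshold artifact
  rejection, anti-aliased resampling.
* **Analyses** — posterior-cluster ERPs; 60-wavelet Gabor
  time–frequency power with common-baseline dB normalization and 8–14
  Hz alpha time courses; per-timepoint LDA decoding with class-balanced
  5-fold cross-validation, 10 iterations, and 40 ms smoothing.
* **Inference** — cluster-based sign-flip permutation tests (exhaustive
  for n ≤ 12, 10,000 flips otherwise), repeated-measures ANOVA and
  paired t with d = t/√n and η²ₚ = df₁F/(df₁F + df₂), signal-detection
  d′/criterion with log-linear correction, Cousineau-Morey
  within-subject SEMs, and the brain–behavior correlation.

Results are tibbles; fitted objects have `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` figures.

## Worked example

Twelve simulated observers, desk-scale design, one-cue evoked gain
twice the two-cue gain (the generator's default hypothesis), full
analysis:

```r
library(attnpipe)

cfg <- pipeline_config("desk", n_subjects = 12, seed = 7)
report <- run_full_pipeline(cfg)
report
```

```
<attnpipe_report> 12 subjects, profile 'desk'
Behavioral tests (one-cue vs two-cue):
  measure   method statistic df1 df2  p_value      d eta_p_sq
 hit_rate paired_t     9.137  11  NA 1.81e-06  2.638       NA
  fa_rate paired_t     1.473  11  NA 1.69e-01  0.425       NA
   hit_rt paired_t    -3.763  11  NA 3.14e-03 -1.086       NA
    cr_rt paired_t    -0.907  11  NA 3.84e-01 -0.262       NA
   dprime paired_t     2.417  11  NA 3.42e-02  0.698       NA
Cluster tests:
  erp_cue_one_vs_two               0 significant cluster(s)
  erp_target_one_vs_two            0 significant cluster(s)
  alpha_one_vs_two                 0 significant cluster(s)
  decoding_cue_one_vs_chance       1 significant cluster(s)
  decoding_cue_two_vs_chance       1 significant cluster(s)
  decoding_cue_one_vs_two          1 significant cluster(s)
  decoding_target_one_vs_chance    0 significant cluster(s)
  decoding_target_two_vs_chance    0 significant cluster(s)
  decoding_target_one_vs_two       0 significant cluster(s)
Brain-behavior correlation:
      window      r df p_value  n
    stimulus  0.449 10   0.143 12
 preparation -0.374 10   0.230 12
```

Reading this output: with a doubled one-cue gain the simulated
observers are more accurate (hit-rate d ≈ 2.6) and faster (hit-RT
d ≈ −1.1) on one-cue trials; the cued color is decodable above the 1/7
chance level from the cue-locked signals and reliably better decoded on
one-cue than on two-cue trials (`decoding_cue_one_vs_two`); and the
stimulus-window brain–behavior correlation is positive (r ≈ 0.45)
though not individually significant at 12 subjects. The target-locked
decoding contrast stays below threshold at this desk scale — 10 target
trials per color and 2 cross-validation iterations are deliberately
minimal; the `full` profile (45 trials per color, 10 iterations, 28
subjects) is the powered version of the same analysis, and the
parameter-recovery suite in `tests/testthat/test-acceptance.R` shows
the target-locked one-cue > two-cue effect emerging reliably at 15
trials per color with the gain ratio held at 2.

Individual stages compose with the pipe:

```r
sched <- build_eeg_schedule(seed = 1)
rec   <- simulate_session(sched, generator_params(), seed = 1)
ep    <- rec |> rereference() |> filter_continuous() |>
  epoch_and_baseline("target") |> reject_artifacts()
acc   <- ep |>
  select_trials(ep$trial_meta$is_target &
                  ep$trial_meta$cue_condition == "one") |>
  prepare_for_decoding() |>
  temporal_decode(k = 5, iterations = 10, seed = 1) |>
  smooth_accuracy()
ggplot2::autoplot(acc) # accuracy time course against the 1/7 chance line
```

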