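---
title: "Modeling and decoding color attentional templates: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and decoding color attentional templates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

attnpipe studies a central question in feature-based attention: how well
can observers keep more than one *attentional template* — a working-memory
representation of a task-relevant feature — active at the same time? The
paradigm is a color-coherence detection task. Each display is a field of
240 dots in five colors. A *noise* field carries all five colors in equal
proportion (0.2 each); a *target* field over-represents one color. With
coherence $P_t$ the four non-target colors each appear with proportion
$P_n = (1 - P_t)/4$, i.e. $P_t = 1 - 4P_n$, so 0.2 is the physical noise
floor of the coherence scale. Before each display, zero to three color
cues tell the observer which color(s) might carry the signal. If
maintaining several templates carries a cost, detection should worsen as
the number of cued colors grows, and the neural representation of the
attended color — readable from posterior EEG with a per-timepoint
classifier — should weaken.

The package implements the complete workflow as testable code: the task
design (dot-field composition, cued trial schedules, adaptive
staircases), a generative model of multichannel EEG and of a behavioral
observer, preprocessing, univariate (ERP, alpha power) and multivariate
(LDA decoding) analyses, cluster-based permutation inference, and the
brain–behavior correlation. Because group-level results from human
recordings cannot be recomputed without the original participants, every
statistic has a synthetic, desk-scale analogue produced by the package's
own generator.

# Task design

`compose_dot_field()` maps `(target_color, coherence)` to integer dot
counts. Ideal counts are floored and the remaining dots assigned by
largest fractional part (target color first on ties) so counts always
sum to the field size; coherence 0.2 reproduces the 48-dots-per-color
noise field.

`build_practice_schedule()` creates the four-condition practice session:
two superblocks, each a random order of the no/one/two/three-cue block
types, 8 blocks of 84 trials, 75% targets — 168 trials per condition
(126 target + 42 noise), cue-to-stimulus interval fixed at 0.8 s.
`build_eeg_schedule()` creates the recording session: 10 alternating
one-cue/two-cue blocks of 84 trials, 45 target and 15 noise trials per
color per condition (315/105 per condition, 840 total), cue-to-stimulus
jitter uniform in [0.8, 1.1] s. Display colors always include the
trial's color and never a cued-but-non-target color
(`select_display_colors()`).

Two design points are genuinely open in this paradigm and were
decided once:

* *Non-target cue assignment.* The additional cue color on two-cue
  trials is assigned by a greedy counterbalancer (always the least-used
  eligible color) separately within target and noise trials, instead of
  an unconstrained random draw. Decoding the non-target cue color with
  class-balanced 5-fold cross-validation requires every color to appear
  at least five times in that role; counterbalancing guarantees this at
  every design scale while leaving the marginal distribution uniform.
* *Cue positions* are sampled as a uniform random rotation with maximal
  angular separation and stored as metadata only; nothing downstream
  consumes them.

## Adaptive staircase

The coherence threshold is estimated with a 2-down-1-up staircase
(`staircase_new()`, `staircase_update()`): two consecutive correct
responses lower coherence by one step, each error raises it, which
converges on the level yielding $\sqrt{0.5} \approx 70.7\%$ correct.
Step size (0.04), start level (0.8), and the rule that only target
trials update the staircase are package choices — noise trials carry no
coherence level to adjust. The level is clamped to $[0.2 +
\text{step}, 1]$ because 0.2 is indistinguishable from noise by
construction. `run_threshold_session()` interleaves seven staircases
(one per palette color) over 5 runs of 84 trials — 60 trials per
staircase — and returns the mean of reversal levels, discarding the
first two reversals when at least six occurred (the initial descent from
the 0.8 start is not representative). Staircases that touch the 1.0
ceiling are flagged as non-converged, mirroring the exclusion of
observers who cannot reach criterion at maximal stimulus strength.

# The synthetic-data generator

`simulate_session()` produces a continuous multichannel record (µV, 500
Hz, 64-channel 10–20 montage by default) that carries exactly the
statistical structure the analyses assume — no more:

* **1/f background**: FFT-shaped noise with spectral exponent 1 and 8 µV
  SD per channel, the canonical broadband EEG background.
* **Posterior alpha**: a 10 Hz, 5 µV oscillation on the 17 posterior
  channels whose amplitude is suppressed by 50% in a smooth window after
  every visual onset (cue and dot-field), emulating event-related alpha
  desynchronization.
* **Color-specific evoked pattern**: each color has a fixed,
  subject-specific, unit-norm channel weight vector concentrated on the
  posterior channels (`color_topography()`; the seven vectors are
  mutually non-collinear by construction). On target trials the target
  color's pattern is added as a Gaussian temporal bump (peak 300 ms,
  FWHM 100 ms) scaled by the *attentional gain* $g_k$ of the cue
  condition and by the coherence excess $(P_t - 0.2)$ — a noise field
  contains nothing to decode. Defaults
  $g_\text{one} = 20 > g_\text{two} = 10 > g_\text{three} = 6$ µV encode
  the weakened-template hypothesis; at a threshold-level coherence of
  0.45 the one-cue component peaks near 5 µV, a realistic visual-ERP
  amplitude against the 8 µV background.
* **Cue/template signal**: during cue display the cued color patterns
  are added (bump of gain 12 µV, halved per color when two cues are
  shown so total cue-display energy is fixed), followed by a weak
  sustained preparatory pattern (2 µV) until stimulus onset. The
  preparatory strength is deliberately exposed as a parameter: evidence
  about its real magnitude is weak, so it is a dial for exploration, not
  a calibrated quantity.
* **Artifacts**: optional Poisson blinks (~350 µV frontal deflections)
  for exercising the rejection rule; off by default.

The behavioral observer (`simulate_observer()`) is a signal-detection
model: evidence $= s_\text{eff}(P_t - 0.2) + \mathcal{N}(0, \sigma)$,
response "target" if evidence exceeds a criterion. Under the
*weakened-template* model $s_\text{eff}$ is the cue condition's template
strength ($s_1 \ge s_2 \ge s_3 \ge s_0$); under the *single-template
switching* model, one cued color is attended per trial (uniformly
drawn), and $s_\text{eff}$ is the one-cue strength when it matches the
presented color and the no-cue strength otherwise — so two-cue
performance is the mixture of the two. Defaults
($s = (1.2, 6, 4.5, 1.2)$ for no/one/two/three, $\sigma = 1$, criterion
0.25) put hit rates near 0.9 and false alarms near 0.4 at threshold
coherence — the regime this task produces when targets appear on 75%
of trials. Response time falls with
the distance of evidence from criterion, with lognormal noise.

What the generator does *not* emulate — realistic ERP component
morphology (P1/N1/P3), eye movements, biophysical volume conduction,
non-stationary impedance drift — bounds what green tests mean: they
validate the analysis chain on data satisfying its assumptions, not the
claim that real cortex behaves this way.

# Preprocessing

The canonical order is re-reference → filter → epoch + baseline →
threshold rejection (`preprocess_record()`):

* Re-referencing subtracts the mean of TP9/TP10 (mastoid
  approximations) sample-wise; the operation is idempotent.
* Filtering is zero-phase (forward–backward) with half-amplitude
  cutoffs at 0.01 and 80 Hz. Each edge is a 2nd-order Butterworth
  section — 12 dB/octave per pass direction — and the forward–backward
  square turns the −3 dB point into the half-amplitude point, the
  ERPLAB convention for quoting cutoffs. Line noise is removed with a
  zero-phase 58–62 Hz band-stop; the contract is ≥ 20 dB attenuation at
  60 Hz, which the tests verify against the measured response rather
  than a specific design method.
* Cue-locked epochs span [−0.5, 3.0] s with baseline [−0.5, 0] s;
  target-locked epochs span [−2.1, 1.4] s with baseline [−2.1, −1.6] s,
  which is approximately the same pre-cue interval given the 0.5 s cue
  and 0.8–1.1 s jitter.
* Rejection removes any trial whose absolute voltage exceeds 200 µV in
  the check window ([−0.5, 2] s cue-locked; full window target-locked).
  The manual visual-inspection step of a human pipeline is not
  reproducible and is deliberately replaced by the deterministic
  threshold rule alone. Rejection never consults trial labels.
* Resampling uses zero-phase decimation for integer factors (exact on
  the original sample grid) and Fourier resampling otherwise; 3.5 s
  epochs at 100 Hz hold 350 samples.

# Univariate analyses

ERPs (`compute_erp()`) average target trials, then the 17 posterior
electrodes (Pz, P1–P8, POz, PO3/4, PO7/8, Oz, O1/2); statistics run on
the electrode-averaged waveform, matching single posterior time-series
plots rather than per-electrode maps.

Time–frequency power (`gabor_tfr()`) uses 60 log-spaced Gabor wavelets
from 2 to 80 Hz with spectral SD $f/5$ (≈5-cycle wavelets) and unit
peak spectral amplitude, so a sinusoid of amplitude $A$ at a center
frequency yields power $A^2/4$; wavelet-bank conventions vary across
toolboxes, so the bank parameters are exposed in the configuration
(`tfr.*`) rather than hard-coded. Single-trial
power is averaged (total power). `baseline_db()` implements the common
baseline: per frequency (and channel), baseline-window power is
averaged over time within condition, then across conditions; every
condition is divided by this common baseline and converted to
$10\log_{10}$ dB. This makes 0 dB mean "at the common baseline" and
the whole measure invariant to global amplitude rescaling. Alpha is
8–14 Hz (`band_power()`).

# Decoding

`prepare_for_decoding()` restricts to the posterior 17 channels,
downsamples to 100 Hz, low-passes at 15 Hz (zero-phase) and applies
Gaussian temporal smoothing with 20 ms FWHM ("a 20-ms window" is read
as FWHM; the parameter is exposed). `temporal_decode()` then trains an
independent multiclass LDA at every time sample: uniform priors, pooled
within-class covariance with a minimal ridge ($10^{-6}$ of the mean
feature variance) for numerical definiteness. Cross-validation is
stratified 5-fold (train 80%, test 20%, folds class-balanced within
each color; after artifact rejection folds stratify on the
post-rejection counts and surplus trials are retained), repeated over
10 re-partitioned iterations and averaged. Chance is 1/7. Accuracy
series receive a 40 ms centered moving mean whose window shrinks
symmetrically at the edges (`smooth_accuracy()`). Fold tables and seeds
are attached to every result, because fold assignment is the only
stochastic element of the analysis.

For two-cue trials the two cue colors are decoded separately — one pass
labeled by the target cue, one by the other cue, with independent
classifiers — and the accuracy series averaged
(`decode_two_cue_colors()`).

# Inference

`cluster_permutation_paired()` and `cluster_permutation_vs_chance()`
implement cluster-based sign-flip permutation tests on time series:
per-sample (paired or one-sample) t statistics, cluster-forming
threshold at two-tailed p < 0.05, clusters as maximal same-sign
suprathreshold runs, cluster mass as the sum of t (sum of t² available
as a sensitivity option), and a max-statistic null over random
per-subject sign flips. For n ≤ 12 subjects the 2ⁿ flips are enumerated
exhaustively and p is the exact tail proportion; otherwise 10,000
Monte-Carlo flips are drawn and p uses the +1 correction so it is never
exactly zero. Zero-variance samples are excluded from cluster formation
with a warning.

Behavioral inference uses `rm_anova_1way()` (via `aov` with an
`Error(subject)` stratum), `paired_t()`, and `sdt_measures()` with the
log-linear correction (0.5 per cell, 1 per denominator) so d′ stays
finite at ceiling — the correction scheme is a package choice made for
determinism. Effect sizes are $d = t/\sqrt{n}$ and $\eta_p^2 =
\mathrm{df}_1 F / (\mathrm{df}_1 F + \mathrm{df}_2)$; these formulas
recompute an analysis's effect sizes exactly to two
decimals from the statistic and sample size alone, which is why they
were adopted over alternatives that differ only via rounding. Error bars use the Cousineau-Morey within-subject
SEM. The brain–behavior analysis correlates (Pearson, two-tailed,
n − 2 df) the one-cue-minus-two-cue hit-rate difference with the
decoding-accuracy difference averaged over the preparatory window
(0.5–1.25 s post-cue) or the stimulus window (target onset to each
subject's condition-specific median RT).

# The pipeline and its profiles

`run_full_pipeline(pipeline_config(profile))` chains everything:
simulate → preprocess → behavior → ERP/alpha → decoding → cluster tests
→ brain–behavior, with TSV/JSON twins of every table
(`write_report()`). A run is a pure function of its configuration; all
randomness derives from the config seed.

Problem sizes are the package's own desk-scale choices, stated here
once: the `desk` profile uses 12 subjects, 10 target + 5 noise trials
per color per condition, a 19-channel montage (the 17 posterior
channels plus TP9/TP10 — the only channels with an analysis role;
simulating the remaining 45 channels adds cost but no information),
500 permutations, 2 decoding iterations, and a 20-wavelet 2–30 Hz bank.
The `full` profile restores the complete design: 28 subjects, 45 + 15
trials per color, 64 channels, 10,000 permutations, 10 iterations, 60
wavelets 2–80 Hz. The acceptance and recovery studies in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` use 45
trials per class for the chance-level study and 15 per class for the
gain-recovery study, with inter-trial bookkeeping shortened to 0.8 s in
signal-free or short-window runs (adjacent epochs then share some
background samples, which is immaterial where no label information
exists outside the analysis window).

# Numerical choices and degenerate inputs

* Dot-count rounding: floor + largest-fraction remainder, target first
  on ties; exact sum preservation.
* LDA ridge $10^{-6}\,\mathrm{tr}(S)/p$: zero covariance stays singular
  (an error advising shrinkage); any within-class variance makes the
  fit defined.
* Permutation p-values: exact tail proportion under exhaustive
  enumeration, +1-corrected under Monte-Carlo.
* dB baseline: zero or negative common baseline power is a guarded
  error, not a NaN.
* Epochs extending beyond the record are dropped with a warning, never
  silently truncated.
* Seeds: every stochastic function takes an explicit seed and restores
  the caller's RNG state; derived seeds stay below 2³¹.

# Known limitations

The generator's evoked model is a single Gaussian bump per trial; it
cannot probe latency effects or component morphology. The switching
observer draws the attended color independently per trial — rhythmic
alternation within a trial is out of scope. The preparatory-period
template signal strength is unconstrained by evidence and defaults to a
small value; preparatory-window decoding results should be read as a
demonstration of the machinery, not a calibrated effect size. HDF5 and
ICA-based blink removal are not implemented: exchange formats are plain
text (TSV/JSON) plus BrainVision for raw records, and artifact handling
is the deterministic threshold rule.
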