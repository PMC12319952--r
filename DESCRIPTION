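Package: attnpipe
Title: Behavioral and EEG Decoding Analysis of Feature-Based Attention to Color
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reproducible pipeline for studying the cost of
    maintaining multiple color attentional templates. Generates the full
    experimental design of a color-coherence detection task (dot-field
    compositions, cued trial schedules, adaptive 2-down-1-up staircases),
    simulates multichannel scalp EEG with 1/f background, posterior alpha
    and color-specific evoked patterns together with a signal-detection
    observer, and analyses the result end to end: re-referencing, zero-phase
    filtering, epoching, threshold artifact rejection, posterior-cluster
    ERPs, Gabor-wavelet alpha power with common-baseline dB normalisation,
    per-timepoint multiclass LDA color decoding under class-balanced
    cross-validation, cluster-based sign-flip permutation inference, and
    brain-behavior correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
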