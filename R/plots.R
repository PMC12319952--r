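#' Plot condition ERPs
#'
#' @param object An `erp_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.erp_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$amplitude,
                                       color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (µV)",
                  color = "Cue condition",
                  title = "Posterior-cluster ERP") +
    ggplot2::theme_minimal()
}

#' Plot a decoding accuracy time course against chance
#'
#' @param object A `decoding_result` tibble (optionally with a
#'   `condition` column).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.decoding_result <- function(object, ...) {
  chance <- attr(object, "chance") %||% (1 / 7)
  aes <- if ("condition" %in% names(object)) {
    ggplot2::aes(x = .data$time, y = .data$accuracy,
                 color = .data$condition)
  } else {
    ggplot2::aes(x = .data$time, y = .data$accuracy)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed",
                        color = "grey40") +
    ggplot2::labs(x = "Time (s)", y = "Classifier accuracy",
                  title = "Per-timepoint color decoding") +
    ggplot2::theme_minimal()
}

#' Plot a cluster test: t time series with significant clusters shaded
#'
#' @param object A `cluster_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_test <- function(object, ...) {
  thr <- qt(1 - object$alpha / 2, object$n_subjects - 1)
  p <- ggplot2::ggplot(object$observed_stat,
                       ggplot2::aes(x = .data$time, y = .data$t)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Paired t",
                  title = "Cluster-based permutation test") +
    ggplot2::theme_minimal()
  sig <- significant_clusters(object)
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_rect(
      data = sig, inherit.aes = FALSE, alpha = 0.2, fill = "firebrick",
      ggplot2::aes(xmin = .data$start_time, xmax = .data$end_time,
                   ymin = -Inf, ymax = Inf)
    )
  }
  p
}

#' Plot condition alpha-power time courses
#'
#' @param band_tc A tibble from [band_power()] (optionally with
#'   `subject`; subjects are averaged).
#' @return A ggplot.
#' @export
plot_alpha_power <- function(band_tc) {
  df <- band_tc |>
    dplyr::group_by(.data$condition, .data$time) |>
    dplyr::summarize(power_db = mean(.data$power_db), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$power_db,
                                   color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "Time (s)", y = "Power (dB re common baseline)",
                  color = "Cue condition", title = "Posterior alpha power") +
    ggplot2::theme_minimal()
}

#' Scatterplot of the brain-behavior cueing effects
#'
#' @param effects A tibble with `hit_effect` and `stim_decoding_effect`
#'   per subject (see the pipeline report's `effects` element).
#' @return A ggplot.
#' @export
plot_brain_behavior <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(x = .data$stim_decoding_effect,
                                        y = .data$hit_effect)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "firebrick") +
    ggplot2::labs(x = "Decoding effect (one-cue - two-cue accuracy)",
                  y = "Hit-rate effect (one-cue - two-cue)",
                  title = "Brain-behavior correlation") +
    ggplot2::theme_minimal()
}
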