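#' Effect sizes from test statistics
#'
#' For a paired t-test, Cohen's d is `t / sqrt(n)`; for a one-way
#' repeated-measures F, partial eta squared is
#' `df1 * F / (df1 * F + df2)`. These recompute the derived effect sizes
#' exactly from the reported statistic and sample size.
#'
#' @param t,f Test statistic.
#' @param n Number of subjects (paired t).
#' @param df1,df2 Numerator / denominator degrees of freedom.
#' @return `cohens_d_from_t()` and `eta_p_sq_from_f()` return a number.
#' @export
cohens_d_from_t <- function(t, n) t / sqrt(n)

#' @rdname cohens_d_from_t
#' @export
eta_p_sq_from_f <- function(f, df1, df2) df1 * f / (df1 * f + df2)

new_effect_size <- function(statistic, df, p, estimate = NULL, d = NA_real_,
                            eta_p_sq = NA_real_, method) {
  structure(
    list(statistic = statistic, df = df, p = p, estimate = estimate,
         d = d, eta_p_sq = eta_p_sq, method = method),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  if (x$method == "rm_anova") {
    cat(sprintf("F(%g, %g) = %.2f, p = %.4g, eta_p^2 = %.2f\n",
                x$df[1], x$df[2], x$statistic, x$p, x$eta_p_sq))
  } else {
    cat(sprintf("t(%g) = %.2f, p = %.4g, d = %.2f\n",
                x$df, x$statistic, x$p, x$d))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.effect_size <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic,
         df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p_value = x$p, d = x$d, eta_p_sq = x$eta_p_sq)
}

#' One-way repeated-measures ANOVA
#'
#' Fits `value ~ condition + Error(subject)` on a complete
#' subject-by-condition design and reports F with
#' `(k - 1, (k - 1)(n - 1))` degrees of freedom plus partial eta squared.
#'
#' @param data Tibble with one row per subject x condition cell.
#' @param value,subject,condition Column names (strings).
#' @return An `effect_size` (method `"rm_anova"`).
#' @export
rm_anova_1way <- function(data, value = "value", subject = "subject",
                          condition = "condition") {
  df <- tibble(
    value = data[[value]],
    subject = factor(data[[subject]]),
    condition = factor(data[[condition]])
  )
  if (anyNA(df$value) ||
      !all(table(df$subject, df$condition) == 1)) {
    abort("Design must be complete: one value per subject x condition.",
          class = "attnpipe_domain_error")
  }
  fit <- aov(value ~ condition + Error(subject), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  f <- tab["condition", "F value"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  p <- tab["condition", "Pr(>F)"]
  new_effect_size(statistic = f, df = c(df1, df2), p = p,
                  eta_p_sq = eta_p_sq_from_f(f, df1, df2),
                  method = "rm_anova")
}

#' Paired (repeated-measures) t-test with Cohen's d
#'
#' Two-tailed paired t-test; `d = t / sqrt(n)`.
#'
#' @param a,b Paired per-subject values.
#' @return An `effect_size` (method `"paired_t"`).
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  if (sd(a - b) == 0) {
    warn("Zero-variance differences: t is infinite.")
    t_val <- if (mean(a - b) == 0) 0 else sign(mean(a - b)) * Inf
    return(new_effect_size(t_val, n - 1, p = if (is.finite(t_val)) 1 else 0,
                           estimate = mean(a - b),
                           d = cohens_d_from_t(t_val, n),
                           method = "paired_t"))
  }
  ht <- t.test(a, b, paired = TRUE)
  new_effect_size(unname(ht$statistic), unname(ht$parameter), ht$p.value,
                  estimate = unname(ht$estimate),
                  d = cohens_d_from_t(unname(ht$statistic), n),
                  method = "paired_t")
}

#' Signal-detection measures from response counts
#'
#' Applies the log-linear extreme-rate correction (0.5 added to each
#' cell, 1 to each denominator) before the z-transform, then
#' `d' = z(H) - z(FA)` and criterion `c = -0.5 (z(H) + z(FA))`, so d' is
#' finite even for perfect performance.
#'
#' @param n_hits,n_misses,n_fas,n_crs Response counts.
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return A tibble: `hit_rate`, `fa_rate`, `dprime`, `criterion`.
#' @export
sdt_measures <- function(n_hits, n_misses, n_fas, n_crs,
                         correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  if (any(c(n_hits, n_misses, n_fas, n_crs) < 0) ||
      (n_hits + n_misses == 0) || (n_fas + n_crs == 0)) {
    abort("Counts must be nonnegative with nonempty signal and noise trials.",
          class = "attnpipe_domain_error")
  }
  if (correction == "loglinear") {
    h <- (n_hits + 0.5) / (n_hits + n_misses + 1)
    fa <- (n_fas + 0.5) / (n_fas + n_crs + 1)
  } else {
    h <- n_hits / (n_hits + n_misses)
    fa <- n_fas / (n_fas + n_crs)
  }
  tibble(hit_rate = h, fa_rate = fa,
         dprime = qnorm(h) - qnorm(fa),
         criterion = -0.5 * (qnorm(h) + qnorm(fa)))
}

#' Within-participant standard errors (Cousineau-Morey)
#'
#' Removes each subject's mean (adding back the grand mean), computes the
#' per-condition SEM of the normalized values, and applies the Morey bias
#' correction `sqrt(k / (k - 1))`. Pure between-subject offsets therefore
#' contribute nothing.
#'
#' @inheritParams rm_anova_1way
#' @return A tibble: `condition`, `mean`, `sem` (corrected).
#' @export
within_subject_sem <- function(data, value = "value", subject = "subject",
                               condition = "condition") {
  df <- tibble(
    value = data[[value]],
    subject = factor(data[[subject]]),
    condition = factor(data[[condition]])
  )
  k <- dplyr::n_distinct(df$condition)
  if (k < 2) {
    warn("Single condition: returning the plain SEM.")
    return(df |> dplyr::group_by(.data$condition) |>
             dplyr::summarize(mean = mean(.data$value),
                              sem = sd(.data$value) / sqrt(dplyr::n()),
                              .groups = "drop"))
  }
  grand <- mean(df$value)
  df |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(norm = .data$value - mean(.data$value) + grand) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarize(
      mean = mean(.data$value),
      sem = sd(.data$norm) / sqrt(dplyr::n()) * sqrt(k / (k - 1)),
      .groups = "drop"
    )
}

#' Brain-behavior correlation
#'
#' Pearson correlation (two-tailed, n - 2 df) between a per-subject
#' behavioral cueing effect (e.g. one-cue minus two-cue hit rate) and the
#' matching neural cueing effect (decoding-accuracy difference averaged
#' over an analysis window).
#'
#' @param behavior_effect,neural_effect Per-subject effect vectors
#'   (same subjects, same order, n >= 4).
#' @return A tibble: `r`, `df`, `p_value`, `n`.
#' @export
brain_behavior_correlation <- function(behavior_effect, neural_effect) {
  stopifnot(length(behavior_effect) == length(neural_effect))
  n <- length(behavior_effect)
  if (n < 4) abort("Need at least 4 subjects.",
                   class = "attnpipe_domain_error")
  if (sd(behavior_effect) == 0 || sd(neural_effect) == 0) {
    abort("Zero variance: correlation undefined.",
          class = "attnpipe_domain_error")
  }
  ht <- cor.test(behavior_effect, neural_effect, method = "pearson")
  tibble(r = unname(ht$estimate), df = unname(ht$parameter),
         p_value = ht$p.value, n = n)
}

#' Window average of a decoding accuracy series
#'
#' @param result A `decoding_result` (or tibble with `time`, `accuracy`).
#' @param window Two-element window in seconds, inclusive.
#' @return Mean accuracy inside the window.
#' @export
window_mean <- function(result, window) {
  sel <- result$time >= window[1] - 1e-9 & result$time <= window[2] + 1e-9
  mean(result$accuracy[sel])
}
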