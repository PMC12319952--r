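#' Prepare epochs for per-timepoint decoding
#'
#' Restricts to the posterior electrode set, downsamples to `rate` Hz,
#' applies a zero-phase low-pass at `lowpass` Hz and Gaussian temporal
#' smoothing (`smooth_fwhm` seconds FWHM).
#'
#' @param epochs An `epoch_set`.
#' @param electrode_set Channels used as features (default posterior 17).
#' @param rate Decoding sample rate (Hz, default 100).
#' @param lowpass Low-pass half-amplitude cutoff (Hz, default 15).
#' @param smooth_fwhm Gaussian smoothing FWHM in seconds (default 0.02).
#' @return The prepared `epoch_set`.
#' @export
prepare_for_decoding <- function(epochs, electrode_set = posterior_17,
                                 rate = 100, lowpass = 15,
                                 smooth_fwhm = 0.02) {
  epochs <- select_channels(epochs, electrode_set)
  epochs <- resample_epochs(epochs, rate)
  lp <- signal::butter(2, lowpass / (epochs$srate / 2), type = "low")
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), d[2])
  for (j in seq_len(ncol(flat))) flat[, j] <- zero_phase(lp, flat[, j])
  if (smooth_fwhm > 0) {
    sdv <- smooth_fwhm / (2 * sqrt(2 * log(2))) * epochs$srate
    half <- max(1L, ceiling(3 * sdv))
    kern <- exp(-((-half):half)^2 / (2 * sdv^2))
    kern <- kern / sum(kern)
    sm <- apply(flat, 2, function(x) {
      as.numeric(stats::filter(x, kern, sides = 2))
    })
    # renormalize shrunken edge windows
    w <- as.numeric(stats::filter(rep(1, d[2]), kern, sides = 2))
    edge <- is.na(sm[, 1])
    for (j in seq_len(ncol(flat))) {
      flat[!edge, j] <- sm[!edge, j] / w[!edge]
    }
  }
  epochs$data <- aperm(array(flat, c(d[2], d[1], d[3])), c(2, 1, 3))
  dimnames(epochs$data) <- list(epochs$channel_names, NULL, NULL)
  epochs
}

#' Multiclass linear discriminant analysis
#'
#' Standard LDA with uniform class priors and a pooled within-class
#' covariance, stabilized by a small ridge (`ridge` times the average
#' feature variance, `trace(S)/p`) so the fit is defined even with
#' near-singular covariance. Deterministic given its inputs.
#'
#' @param features Numeric matrix, trials x features.
#' @param labels Class label per trial.
#' @param ridge Relative ridge (default `1e-6`); `0` disables shrinkage,
#'   in which case a singular covariance is an error advising shrinkage.
#' @return An `lda_model` with `predict()` support.
#' @export
train_lda <- function(features, labels, ridge = 1e-6) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (any(table(labels) < 2)) {
    abort("Every class needs at least 2 training trials.",
          class = "attnpipe_domain_error")
  }
  p <- ncol(features)
  M <- t(vapply(classes, function(k) colMeans(features[labels == k, ,
                                                       drop = FALSE]),
                numeric(p)))
  centered <- features - M[match(labels, classes), , drop = FALSE]
  S <- crossprod(centered) / (nrow(features) - length(classes))
  if (ridge > 0) S <- S + diag(ridge * sum(diag(S)) / p, p)
  Sinv <- tryCatch(solve(S), error = function(e) {
    abort("Pooled covariance is singular; use a positive `ridge`.",
          class = "attnpipe_numeric_error")
  })
  W <- Sinv %*% t(M)                       # p x K
  b <- -0.5 * colSums(t(M) * W)            # K
  structure(list(classes = classes, W = W, b = b, means = M, cov = S),
            class = "lda_model")
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  scores <- as.matrix(newdata) %*% object$W +
    rep(object$b, each = nrow(as.matrix(newdata)))
  object$classes[max.col(scores, ties.method = "first")]
}

# Stratified fold assignment: within each class, trials are shuffled and
# dealt round-robin over k folds (surplus trials retained, fold sizes
# within a class differ by at most one).
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      abort(sprintf("Class '%s' has %d trials, fewer than k = %d.",
                    cl, length(idx), k),
            class = "attnpipe_stratification_error")
    }
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Per-timepoint color decoding with class-balanced cross-validation
#'
#' At every time sample, trains a multiclass LDA on the channel pattern
#' and evaluates held-out proportion correct under stratified k-fold
#' cross-validation; the fold partition is re-drawn `iterations` times
#' and accuracies averaged. Identical seeds give identical fold
#' assignments and results.
#'
#' @param epochs A prepared `epoch_set` (see [prepare_for_decoding()]).
#' @param labels Class label per trial (e.g. target color); defaults to
#'   `trial_meta$target_color`.
#' @param k Folds (default 5: train on 80%, test on 20%).
#' @param iterations Number of re-partitioned repeats (default 10).
#' @param seed Integer seed for the fold partitions.
#' @param ridge Passed to [train_lda()].
#' @return A `decoding_result` tibble (`time`, `accuracy`) with
#'   attributes `chance` (1/number of classes), `k`, `iterations`, and
#'   the fold table (`attr(,"folds")`: iteration, trial, fold).
#' @export
temporal_decode <- function(epochs, labels = NULL, k = 5, iterations = 10,
                            seed = 1, ridge = 1e-6) {
  if (is.null(labels)) labels <- epochs$trial_meta$target_color
  labels <- as.character(labels)
  d <- dim(epochs$data)
  stopifnot(length(labels) == d[3])
  classes <- sort(unique(labels))
  acc <- numeric(d[2])
  fold_tbl <- vector("list", iterations)
  with_rng(seed, {
    for (it in seq_len(iterations)) {
      folds <- stratified_folds(labels, k)
      fold_tbl[[it]] <- tibble(iteration = it, trial = seq_len(d[3]),
                               fold = folds)
      acc_it <- numeric(d[2])
      for (f in seq_len(k)) {
        tr <- folds != f
        te <- !tr
        fold_acc <- vapply(seq_len(d[2]), function(t_i) {
          X <- t(epochs$data[, t_i, , drop = TRUE])
          fit <- train_lda(X[tr, , drop = FALSE], labels[tr], ridge)
          mean(predict(fit, X[te, , drop = FALSE]) == labels[te])
        }, numeric(1))
        acc_it <- acc_it + fold_acc / k
      }
      acc <- acc + acc_it / iterations
    }
  })
  out <- tibble(time = epochs$times, accuracy = acc)
  structure(out, chance = 1 / length(classes), k = k,
            iterations = iterations, seed = seed,
            folds = dplyr::bind_rows(fold_tbl),
            class = c("decoding_result", class(out)))
}

#' Decode the two cued colors of two-cue trials
#'
#' Runs [temporal_decode()] twice — once labeling every trial by the
#' target cue color and once by the other (non-target) cue — with
#' independent classifiers, and averages the two accuracy series.
#'
#' @param epochs A prepared `epoch_set` of two-cue trials whose metadata
#'   carries `cued_colors` (pairs) and `target_color`.
#' @inheritParams temporal_decode
#' @return A `decoding_result` tibble.
#' @export
decode_two_cue_colors <- function(epochs, k = 5, iterations = 10, seed = 1,
                                  ridge = 1e-6) {
  meta <- epochs$trial_meta
  pair_ok <- vapply(meta$cued_colors, length, integer(1)) == 2
  if (!all(pair_ok)) {
    abort("Every trial must carry exactly two cued colors.",
          class = "attnpipe_label_error")
  }
  lab_target <- meta$target_color
  lab_other <- vapply(seq_len(nrow(meta)), function(i) {
    setdiff(meta$cued_colors[[i]], meta$target_color[i])[1]
  }, character(1))
  r1 <- temporal_decode(epochs, lab_target, k, iterations,
                        seed = child_seed(seed, 1), ridge = ridge)
  r2 <- temporal_decode(epochs, lab_other, k, iterations,
                        seed = child_seed(seed, 2), ridge = ridge)
  out <- tibble(time = r1$time, accuracy = (r1$accuracy + r2$accuracy) / 2)
  structure(out, chance = attr(r1, "chance"), k = k,
            iterations = iterations, seed = seed,
            class = c("decoding_result", class(out)))
}

#' Moving-mean smoothing of a decoding accuracy series
#'
#' Centered moving mean over `window` seconds; at the series edges the
#' window shrinks symmetrically, so a constant series is unchanged and
#' total mass is preserved.
#'
#' @param result A `decoding_result` (or any tibble with `time` and
#'   `accuracy`).
#' @param window Smoothing window in seconds (default 0.04).
#' @return The smoothed result (same class and attributes).
#' @export
smooth_accuracy <- function(result, window = 0.04) {
  dt <- median(diff(result$time))
  if (window < dt) return(result)
  half <- floor(round(window / dt) / 2)
  if (half == 0) return(result)
  x <- result$accuracy
  n <- length(x)
  sm <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i) # symmetric shrink at the edges
    mean(x[(i - h):(i + h)])
  }, numeric(1))
  result$accuracy <- sm
  result
}
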