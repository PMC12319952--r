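# Maximal runs of suprathreshold same-sign t-values and their masses.
find_clusters <- function(tvec, thr, mass = c("sum_t", "sum_t2")) {
  mass <- match.arg(mass)
  lab <- integer(length(tvec))
  lab[tvec > thr] <- 1L
  lab[tvec < -thr] <- -1L
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep)) {
    return(tibble(start = integer(), end = integer(), mass = numeric()))
  }
  m <- vapply(which(keep), function(j) {
    seg <- tvec[starts[j]:ends[j]]
    if (mass == "sum_t") sum(seg) else sum(seg^2) * sign(seg[1])
  }, numeric(1))
  tibble(start = starts[keep], end = ends[keep], mass = m)
}

max_cluster_mass <- function(tvec, thr, mass) {
  cl <- find_clusters(tvec, thr, mass)
  if (nrow(cl) == 0) 0 else max(abs(cl$mass))
}

# Sign-flip matrix: exhaustive (2^n rows, identity first) for n <= 12,
# otherwise n_perm Monte-Carlo draws.
sign_flips <- function(n, n_perm) {
  if (n <= 12) {
    grid <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(grid) <- NULL
    list(S = grid, exhaustive = TRUE)
  } else {
    S <- matrix(sample(c(1, -1), n * n_perm, replace = TRUE), n_perm, n)
    list(S = S, exhaustive = FALSE)
  }
}

cluster_test_core <- function(X, times, n_perm, alpha, seed, mass,
                              method) {
  n <- nrow(X)
  if (n < 5) abort("Need at least 5 subjects.",
                   class = "attnpipe_domain_error")
  nt <- ncol(X)
  q <- colSums(X^2)
  m_obs <- colMeans(X)
  v_obs <- (q - n * m_obs^2) / (n - 1)
  zero_var <- v_obs <= .Machine$double.eps * pmax(q, 1)
  if (any(zero_var)) {
    warn(sprintf("%d zero-variance sample(s) excluded from cluster formation.",
                 sum(zero_var)))
  }
  t_obs <- ifelse(zero_var, 0, m_obs / sqrt(v_obs / n))
  thr <- qt(1 - alpha / 2, n - 1)
  clusters <- find_clusters(t_obs, thr, mass)

  p_values <- numeric(nrow(clusters))
  n_used <- 0L
  exhaustive <- FALSE
  if (nrow(clusters) > 0) {
    res <- with_rng(seed, sign_flips(n, n_perm))
    S <- res$S
    exhaustive <- res$exhaustive
    n_used <- nrow(S)
    M <- (S %*% X) / n
    V <- sweep(-n * M^2, 2, q, "+") / (n - 1)
    V[V < 0] <- 0
    Tm <- M / sqrt(V / n)
    Tm[, zero_var] <- 0
    Tm[!is.finite(Tm)] <- 0
    null_max <- vapply(seq_len(n_used), function(i) {
      max_cluster_mass(Tm[i, ], thr, mass)
    }, numeric(1))
    p_values <- vapply(abs(clusters$mass), function(ms) {
      ge <- sum(null_max >= ms - 1e-12)
      if (exhaustive) ge / n_used else (1 + ge) / (1 + n_used)
    }, numeric(1))
  }

  clusters <- clusters |>
    dplyr::mutate(
      start_time = times[.data$start], end_time = times[.data$end],
      p_value = p_values, .before = "mass"
    )
  structure(
    list(clusters = clusters,
         observed_stat = tibble(time = times, t = t_obs),
         n_permutations = n_used, exhaustive = exhaustive,
         alpha = alpha, tail = "two", mass = mass, method = method,
         n_subjects = n),
    class = "cluster_test"
  )
}

#' Cluster-based sign-flip permutation test (paired)
#'
#' Per-sample paired t-statistics on the subject-wise difference of two
#' time series; clusters are maximal runs of contiguous samples exceeding
#' the two-tailed `alpha` t-threshold (positive and negative runs
#' separate), with mass the sum of t-values in the run. The null
#' distribution of the maximal absolute cluster mass is built from random
#' per-subject sign flips of the difference — exhaustively (all `2^n`
#' flips) for n <= 12, otherwise from `n_perm` Monte-Carlo flips with the
#' +1-corrected p-value `(1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param a,b Numeric matrices, subjects x time (equal time axes).
#' @param times Time axis (defaults to sample indices).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param alpha Cluster-forming threshold, two-tailed (default 0.05).
#' @param seed Integer seed for Monte-Carlo flips.
#' @param mass `"sum_t"` (default) or `"sum_t2"` cluster mass.
#' @return A `cluster_test` object; `tidy()` gives the cluster table.
#' @export
cluster_permutation_paired <- function(a, b, times = NULL, n_perm = 10000,
                                       alpha = 0.05, seed = 1,
                                       mass = c("sum_t", "sum_t2")) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)))
  if (is.null(times)) times <- seq_len(ncol(a))
  cluster_test_core(a - b, times, n_perm, alpha, seed, match.arg(mass),
                    method = "paired")
}

#' @rdname cluster_permutation_paired
#' @param accuracy Numeric matrix, subjects x time, of decoding accuracy.
#' @param chance Chance level subtracted before the one-sample test
#'   (default 1/7).
#' @export
cluster_permutation_vs_chance <- function(accuracy, chance = 1 / 7,
                                          times = NULL, n_perm = 10000,
                                          alpha = 0.05, seed = 1,
                                          mass = c("sum_t", "sum_t2")) {
  accuracy <- as.matrix(accuracy)
  if (is.null(times)) times <- seq_len(ncol(accuracy))
  cluster_test_core(accuracy - chance, times, n_perm, alpha, seed,
                    match.arg(mass), method = "one_sample_vs_chance")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %s, n = %d subjects, %s null (%d flips)\n",
              x$method, x$n_subjects,
              if (x$exhaustive) "exhaustive sign-flip" else "Monte-Carlo",
              x$n_permutations))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    print(as.data.frame(x$clusters[, c("start_time", "end_time", "mass",
                                       "p_value")]), row.names = FALSE)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_test <- function(x, ...) x$clusters

#' @exportS3Method generics::glance
glance.cluster_test <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$p_value < x$alpha),
    min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_,
    n_permutations = x$n_permutations,
    exhaustive = x$exhaustive,
    alpha = x$alpha
  )
}

#' Significant cluster intervals
#'
#' @param x A `cluster_test`.
#' @param alpha Significance level (defaults to the test's alpha).
#' @return Tibble of clusters with `p_value < alpha`.
#' @export
significant_clusters <- function(x, alpha = x$alpha) {
  x$clusters[x$clusters$p_value < alpha, ]
}
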