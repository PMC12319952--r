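# Shared fixture builders; everything is generated in code at test time.

toy_record <- function(data, srate = 500, channels = NULL,
                       events = NULL, schedule = NULL) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("Ch", seq_len(nrow(data)))
  rownames(data) <- channels
  if (is.null(events)) {
    events <- tibble::tibble(trial = integer(), event = character(),
                             onset = numeric())
  }
  if (is.null(schedule)) schedule <- tibble::tibble(trial = events$trial)
  structure(list(data = data, srate = srate, channel_names = channels,
                 events = events, schedule = schedule),
            class = "eeg_record")
}

toy_epochs <- function(data, srate = 500, times = NULL, lock = "cue",
                       channels = NULL, meta = NULL) {
  d <- dim(data)
  if (is.null(channels)) channels <- paste0("Ch", seq_len(d[1]))
  if (is.null(times)) times <- (seq_len(d[2]) - 1) / srate
  if (is.null(meta)) meta <- tibble::tibble(trial = seq_len(d[3]))
  new_epochs(data, srate, times, lock, channels, meta)
}

# Epochs over the 17 posterior channels with a class-specific spatial
# pattern inside [sig_from, sig_to]; labels balanced over `classes`.
pattern_epochs <- function(n_per_class = 8, classes = color_palette(),
                           srate = 100, n_time = 60, amp = 3,
                           noise_sd = 1, sig_idx = 20:35, seed = 1,
                           channels = posterior_17) {
  n_ch <- length(channels)
  n_tr <- n_per_class * length(classes)
  labels <- rep(classes, each = n_per_class)
  withr::with_seed(seed, {
    pat <- matrix(rnorm(n_ch * length(classes)), n_ch)
    data <- array(rnorm(n_ch * n_time * n_tr, sd = noise_sd),
                  c(n_ch, n_time, n_tr))
    for (i in seq_len(n_tr)) {
      k <- match(labels[i], classes)
      data[, sig_idx, i] <- data[, sig_idx, i] + amp * pat[, k]
    }
    list(epochs = toy_epochs(data, srate = srate, channels = channels,
                             meta = tibble::tibble(trial = seq_len(n_tr),
                                                   target_color = labels)),
         labels = labels, patterns = pat)
  })
}

# Naive, independently-coded Gaussian discriminant classifier used as the
# brute-force oracle for LDA-based cross-validation.
naive_lda_predict <- function(Xtr, ytr, Xte, ridge = 1e-6) {
  classes <- sort(unique(ytr))
  p <- ncol(Xtr)
  mats <- lapply(classes, function(k) Xtr[ytr == k, , drop = FALSE])
  mus <- lapply(mats, colMeans)
  Sp <- matrix(0, p, p)
  for (j in seq_along(mats)) {
    cc <- sweep(mats[[j]], 2, mus[[j]])
    Sp <- Sp + t(cc) %*% cc
  }
  Sp <- Sp / (nrow(Xtr) - length(classes))
  Sp <- Sp + diag(ridge * sum(diag(Sp)) / p, p)
  Si <- solve(Sp)
  scores <- sapply(seq_along(classes), function(j) {
    as.numeric(Xte %*% Si %*% mus[[j]] -
                 0.5 * as.numeric(t(mus[[j]]) %*% Si %*% mus[[j]]))
  })
  classes[apply(matrix(scores, nrow = nrow(Xte)), 1, which.max)]
}

# Independent brute-force cluster permutation oracle (exhaustive flips).
brute_cluster_p <- function(X, alpha = 0.05) {
  n <- nrow(X)
  tser <- function(M) {
    apply(M, 2, function(v) {
      s <- sd(v)
      if (s == 0) 0 else mean(v) / (s / sqrt(length(v)))
    })
  }
  thr <- qt(1 - alpha / 2, n - 1)
  segs <- function(tv) {
    lab <- ifelse(tv > thr, 1L, ifelse(tv < -thr, -1L, 0L))
    out <- list(); cur <- NULL
    for (i in seq_along(lab)) {
      if (lab[i] != 0L && (is.null(cur) || lab[i] == cur$sign)) {
        if (is.null(cur)) cur <- list(sign = lab[i], idx = i)
        else cur$idx <- c(cur$idx, i)
      } else {
        if (!is.null(cur)) out[[length(out) + 1]] <- cur
        cur <- if (lab[i] != 0L) list(sign = lab[i], idx = i) else NULL
      }
    }
    if (!is.null(cur)) out[[length(out) + 1]] <- cur
    out
  }
  obs <- tser(X)
  cl <- segs(obs)
  if (length(cl) == 0) return(NULL)
  masses <- vapply(cl, function(c0) sum(obs[c0$idx]), numeric(1))
  flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null_max <- apply(flips, 1, function(s) {
    tv <- tser(X * s)
    cs <- segs(tv)
    if (length(cs) == 0) 0 else max(abs(vapply(cs, function(c0)
      sum(tv[c0$idx]), numeric(1))))
  })
  data.frame(
    start = vapply(cl, function(c0) min(c0$idx), numeric(1)),
    end = vapply(cl, function(c0) max(c0$idx), numeric(1)),
    mass = masses,
    p = vapply(abs(masses), function(m) mean(null_max >= m - 1e-12),
               numeric(1))
  )
}
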