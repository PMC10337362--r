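# Independent oracles and fixture builders used across the suite.

# Exhaustive DTW: enumerate every monotone warping path by plain recursion.
# Exponential, so only for sequences of length <= ~7; this is the reference
# the dynamic-programming implementation is validated against.
dtw_enum <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  d <- function(i, j) sqrt(sum((a[i, 1:2] - b[j, 1:2])^2))
  rec <- function(i, j) {
    c0 <- d(i, j)
    if (i == n && j == m) return(c0)
    opts <- c(
      if (i < n) rec(i + 1, j),
      if (j < m) rec(i, j + 1),
      if (i < n && j < m) rec(i + 1, j + 1))
    c0 + min(opts)
  }
  rec(1, 1)
}

# Direct discrete Gaussian convolution with symmetric (edge-including)
# reflection, the boundary rule gaussian_smooth() documents.
conv_oracle <- function(v, sigma) {
  r <- max(1, ceiling(4 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2)); w <- w / sum(w)
  n <- length(v)
  vapply(seq_len(n), function(i) {
    idx <- (i - r):(i + r)
    idx <- ifelse(idx < 1, 1 - idx, idx)
    idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
    sum(w * v[idx])
  }, numeric(1))
}

# Independent transcription of the key-point restructuring rule, used to
# cross-check temporal_restructure on random clusterings.
restructure_oracle <- function(clusters) {
  means0 <- sort(vapply(clusters, `[[`, numeric(1), "mean_t"))
  clusters <- clusters[order(vapply(clusters, `[[`, numeric(1), "mean_t"))]
  k <- length(clusters)
  out <- list()
  for (i in seq_len(k)) {
    p <- clusters[[i]]$points
    lo <- if (i > 1) means0[i - 1] else -Inf
    hi <- if (i < k) means0[i + 1] else Inf
    p <- p[p$t >= lo & p$t <= hi, , drop = FALSE]
    if (nrow(p))
      out[[length(out) + 1L]] <- c(mean(p$x), mean(p$y), mean(p$t), nrow(p))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("cx", "cy", "mean_t", "n_points")
  df[order(df$mean_t), , drop = FALSE]
}

# Simple trajectory builders ------------------------------------------------

make_traj <- function(x, y, pressure, t, sid = "t1", part = "A", block = 2) {
  trajectory(x, y, pressure, t, subject_id = sid, part = part, block = block)
}

# Minimum-jerk point-to-point segment, optionally with sinusoidal tremor,
# all pen-down, uniformly sampled. The analytic baseline for jerk tests.
minjerk_traj <- function(dur = 2, from = c(2000, 2000), to = c(12000, 8000),
                         amp = 0, freq = 8, rate = 100, pressure = 1000,
                         sid = "mj") {
  t <- seq(0, dur, by = 1 / rate)
  tau <- t / dur
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  x <- from[1] + (to[1] - from[1]) * s
  y <- from[2] + (to[2] - from[2]) * s
  if (amp > 0) {
    x <- x + amp * sin(2 * pi * freq * t)
    y <- y + amp * sin(2 * pi * freq * t + 1)
  }
  make_traj(x, y, rep(pressure, length(t)), t, sid = sid)
}

# Short random trajectory for DTW / template-selection oracle tests.
random_short_traj <- function(len, sid) {
  make_traj(runif(len, 0, 21000), runif(len, 0, 29700),
            rep(1000, len), seq(0, by = 0.1, length.out = len), sid = sid)
}

# Random raw clusterings (via vq_cluster on scattered points).
random_clustering <- function(n = 120, k = 6, seed = 1) {
  set.seed(seed)
  pts <- data.frame(x = runif(n, 0, 21000), y = runif(n, 0, 29700),
                    t = sort(runif(n, 0, 60)) + runif(n, -10, 10))
  vq_cluster(pts, k = k, seed = seed + 1)
}

# Synthetic feature table for classifier tests.
make_feature_table <- function(n_per_class = 30, n_noise = 10, shift = 0,
                               labels = c("HC", "AD"), seed = 1) {
  set.seed(seed)
  n <- n_per_class * 2
  lab <- rep(labels, each = n_per_class)
  tab <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                    label = factor(lab, levels = c("HC", "MCI", "AD")))
  tab$signal <- rnorm(n) + shift * (lab == labels[2])
  for (i in seq_len(n_noise)) tab[[paste0("noise", i)]] <- rnorm(n)
  structure(tab, class = c("tmt_features", "data.frame"))
}

clear_tmtrace_cache <- function() {
  env <- get(".template_cache", envir = asNamespace("tmtrace"))
  rm(list = ls(envir = env), envir = env)
}
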