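#' Gaussian smoothing of a trajectory
#'
#' Filters the x and y coordinate streams independently with a discrete
#' Gaussian kernel over sample index (reflect boundary); pressure and
#' timestamps are untouched. `sigma` is in sample-index units; the default
#' `0.1` — the value used for reference trajectories before key-point
#' extraction — is nearly an identity at typical sampling rates, and
#' `sigma = 0` is the exact identity.
#'
#' @param traj a [trajectory()].
#' @param sigma kernel standard deviation in samples, `>= 0`.
#' @return A smoothed trajectory with the same metadata.
#' @export
gaussian_smooth <- function(traj, sigma = 0.1) {
  stopifnot(is_trajectory(traj), sigma >= 0)
  if (sigma == 0) return(traj)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  out <- traj
  out$x <- reflect_convolve(traj$x, w, r)
  out$y <- reflect_convolve(traj$y, w, r)
  out
}

reflect_convolve <- function(v, w, r) {
  n <- length(v)
  # reflect about the edge samples (scipy-style 'reflect': abcd -> dcba|abcd|dcba)
  pre <- v[pmin(pmax(rev(seq_len(r)), 1L), n)]
  post <- v[pmax(pmin(n + 1L - seq_len(r), n), 1L)]
  padded <- c(pre, v, post)
  out <- numeric(n)
  for (k in seq_along(w)) out <- out + w[k] * padded[(k - 1L) + seq_len(n)]
  out
}

#' Vector-quantize the pen-down points of a trajectory
#'
#' k-means clustering of the pen-down (x, y) points — spatial distribution
#' only, timestamps are carried along but never enter the distance — with a
#' k-means++-style seeded initialisation. The codebook size defaults to 40.
#' If Lloyd iteration empties a cluster the fit is restarted with a fresh
#' initialisation (up to 10 times), after which empty clusters are dropped.
#' The effective k is capped at the number of distinct points.
#'
#' @param points data frame with columns `x`, `y`, `t` (pen-down samples).
#' @param k codebook size.
#' @param seed integer seed controlling initialisation.
#' @return List of raw clusters, each `list(points = <data frame>, center =
#'   c(x, y), mean_t = <s>, n = <count>)`, ordered by `mean_t`.
#' @export
vq_cluster <- function(points, k = 40L, seed = 1L) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y", "t") %in% names(points)))
  if (nrow(points) < 1) stop("no pen-down points to cluster")
  xy <- as.matrix(points[, c("x", "y")])
  k_eff <- min(as.integer(k), nrow(unique(xy)))
  local_seed(seed, {
    cl <- NULL
    for (attempt in seq_len(10L)) {
      centers <- kmeanspp_init(xy, k_eff)
      fit <- suppressWarnings(kmeans(xy, centers = centers, iter.max = 100L,
                                     algorithm = "Lloyd"))
      cl <- fit
      if (all(fit$size > 0)) break
    }
    keep <- which(cl$size > 0)
    clusters <- lapply(keep, function(g) {
      idx <- which(cl$cluster == g)
      list(points = points[idx, c("x", "y", "t"), drop = FALSE],
           center = c(mean(points$x[idx]), mean(points$y[idx])),
           mean_t = mean(points$t[idx]), n = length(idx))
    })
    clusters[order(vapply(clusters, `[[`, numeric(1), "mean_t"))]
  })
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_init <- function(xy, k) {
  n <- nrow(xy)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1) {
    d2 <- colSums((t(xy) - xy[idx[1], ])^2)
    for (i in 2:k) {
      d2[d2 < .Machine$double.eps] <- 0
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[i] <- sample.int(n, 1L, prob = probs)
      d2 <- pmin(d2, colSums((t(xy) - xy[idx[i], ])^2))
    }
  }
  # nudge exact duplicates so stats::kmeans accepts the center matrix
  centers <- xy[idx, , drop = FALSE]
  dup <- duplicated(centers)
  if (any(dup))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(runif(2 * sum(dup), -1e-6, 1e-6), ncol = 2)
  centers
}

#' Temporal restructuring of raw clusters into key points
#'
#' Spatial k-means can absorb points that are far from a cluster's
#' companions in time (e.g. a stroke revisiting a region), dragging the
#' center away from the pass it represents. Restructuring orders clusters
#' by their mean timestamp and, in a single pass using the original
#' neighbour means, removes from cluster i the member points earlier than
#' the mean time of cluster i-1 or later than the mean time of cluster i+1.
#' Clusters emptied by the removal are dropped; centers and mean times are
#' recomputed from the survivors. The surviving clusters are then ordered
#' by their new mean time, merging exact ties, so the key-point sequence is
#' strictly increasing in time.
#'
#' @param clusters raw clusters from [vq_cluster()].
#' @return A `tmt_keypoints` object: data frame with columns `idx`, `cx`,
#'   `cy`, `mean_t`, `n_points` (weights are attached by
#'   [extract_keypoints()], which knows the pen-down denominator).
#' @export
temporal_restructure <- function(clusters) {
  if (!length(clusters)) stop("no clusters to restructure")
  means0 <- vapply(clusters, `[[`, numeric(1), "mean_t")
  ord <- order(means0)
  clusters <- clusters[ord]; means0 <- means0[ord]
  k <- length(clusters)
  pruned <- vector("list", k)
  for (i in seq_len(k)) {
    p <- clusters[[i]]$points
    keep <- rep(TRUE, nrow(p))
    if (i > 1) keep <- keep & p$t >= means0[i - 1]
    if (i < k) keep <- keep & p$t <= means0[i + 1]
    pruned[[i]] <- p[keep, , drop = FALSE]
  }
  pruned <- pruned[vapply(pruned, nrow, integer(1)) > 0]
  if (!length(pruned)) stop("temporal restructuring emptied every cluster")
  kp <- data.frame(
    cx = vapply(pruned, function(p) mean(p$x), numeric(1)),
    cy = vapply(pruned, function(p) mean(p$y), numeric(1)),
    mean_t = vapply(pruned, function(p) mean(p$t), numeric(1)),
    n_points = vapply(pruned, nrow, integer(1)))
  kp <- kp[order(kp$mean_t), , drop = FALSE]
  # merge exact mean-time ties so mean_t is strictly increasing
  if (anyDuplicated(kp$mean_t)) {
    grp <- match(kp$mean_t, unique(kp$mean_t))
    kp <- do.call(rbind, lapply(split(kp, grp), function(g) data.frame(
      cx = sum(g$cx * g$n_points) / sum(g$n_points),
      cy = sum(g$cy * g$n_points) / sum(g$n_points),
      mean_t = g$mean_t[1], n_points = sum(g$n_points))))
    kp <- kp[order(kp$mean_t), , drop = FALSE]
  }
  rownames(kp) <- NULL
  kp <- cbind(idx = seq_len(nrow(kp)), kp)
  structure(kp, class = c("tmt_keypoints", "data.frame"))
}

#' Extract the key-point sequence of a trajectory
#'
#' The template-comparison representation: Gaussian smoothing, pen-down
#' filtering, vector quantization ([vq_cluster()]) and temporal
#' restructuring ([temporal_restructure()]). Each key point carries a
#' relative weight — its member count divided by the trajectory's pen-down
#' sample count — quantifying how much of the trace the key point stands
#' for.
#'
#' @param traj a [trajectory()].
#' @param k codebook size (default 40).
#' @param sigma smoothing parameter in samples (default 0.1).
#' @param seed integer seed for the clustering initialisation.
#' @return A `tmt_keypoints` data frame with columns `idx`, `cx`, `cy`,
#'   `mean_t`, `n_points`, `weight`, plus attributes `subject_id`, `part`,
#'   `block`, `k`, `sigma`, `seed`.
#' @export
extract_keypoints <- function(traj, k = 40L, sigma = 0.1, seed = 1L) {
  stopifnot(is_trajectory(traj))
  sm <- gaussian_smooth(traj, sigma)
  pend <- as.data.frame(sm)[sm$pressure > 0, c("x", "y", "t"), drop = FALSE]
  if (!nrow(pend)) stop("trajectory has no pen-down points")
  clusters <- vq_cluster(pend, k = k, seed = seed)
  kp <- temporal_restructure(clusters)
  kp$weight <- kp$n_points / nrow(pend)
  attr(kp, "subject_id") <- attr(traj, "subject_id")
  attr(kp, "part") <- attr(traj, "part")
  attr(kp, "block") <- attr(traj, "block")
  attr(kp, "k") <- as.integer(k)
  attr(kp, "sigma") <- sigma
  attr(kp, "seed") <- as.integer(seed)
  kp
}
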