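#' Dynamic time warping distance between 2-D point sequences
#'
#' `dtw_distance()` is the exact dynamic-programming DTW: the minimal sum of
#' Euclidean local costs over all monotone alignments of the two sequences
#' (no band constraint, no path-length normalisation). It is symmetric,
#' nonnegative and zero exactly for identical sequences.
#'
#' `fast_dtw_distance()` is the multilevel coarse-to-fine approximation:
#' the sequences are recursively halved, the coarse optimal path is
#' projected back to the finer resolution and inflated by `radius` cells,
#' and DTW is re-solved inside that band. With `radius >= max(n, m)` the
#' band covers the whole matrix and the result equals `dtw_distance()`
#' exactly; small radii trade a bounded approximation error for near-linear
#' runtime on long trajectories.
#'
#' @param a,b point sequences: two-column matrices / data frames of (x, y),
#'   or [trajectory()] objects (their x/y columns are used).
#' @param radius band inflation radius (cells), `>= 1`.
#' @return Nonnegative scalar distance in device units.
#' @examples
#' a <- cbind(x = 0:3, y = 0)
#' b <- cbind(x = c(0, 3), y = 0)
#' dtw_distance(a, b)
#' fast_dtw_distance(a, b, radius = 4) # full band: exact
#' @export
dtw_distance <- function(a, b) {
  a <- as_xy(a); b <- as_xy(b)
  .dtw_cost_full(a[, 1], a[, 2], b[, 1], b[, 2])
}

as_xy <- function(p) {
  if (is_trajectory(p)) p <- cbind(p$x, p$y)
  p <- as.matrix(p)
  if (is.null(dim(p)) || ncol(p) < 2) stop("point sequence must have x and y columns")
  if (nrow(p) < 1) stop("point sequence must be nonempty")
  storage.mode(p) <- "double"
  p[, 1:2, drop = FALSE]
}

#' @rdname dtw_distance
#' @export
fast_dtw_distance <- function(a, b, radius = 1L) {
  a <- as_xy(a); b <- as_xy(b)
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1")
  fastdtw_rec(a, b, radius)$cost
}

fastdtw_rec <- function(a, b, radius) {
  n <- nrow(a); m <- nrow(b)
  min_size <- radius + 2L
  if (n <= min_size || m <= min_size) {
    return(.dtw_cost_window(a[, 1], a[, 2], b[, 1], b[, 2],
                            rep(1L, n), rep(m, n)))
  }
  coarse <- fastdtw_rec(halve_seq(a), halve_seq(b), radius)
  win <- expand_window(coarse$path, n, m, radius)
  .dtw_cost_window(a[, 1], a[, 2], b[, 1], b[, 2], win$jmin, win$jmax)
}

# coarsen by averaging consecutive pairs; an odd trailing point is kept as is
halve_seq <- function(p) {
  n <- nrow(p)
  k <- n %/% 2L
  q <- (p[2 * seq_len(k) - 1L, , drop = FALSE] +
          p[2 * seq_len(k), , drop = FALSE]) / 2
  if (n %% 2L == 1L) q <- rbind(q, p[n, , drop = FALSE])
  q
}

# Project a coarse path onto the finer grid (each coarse cell covers a 2x2
# block of fine cells) and inflate by `radius` in both directions. Because a
# monotone coarse path visits every coarse row and the blocks of consecutive
# path cells touch at least diagonally, the resulting per-row column band
# covers every fine row, contains (1,1) and (n,m), and admits a monotone
# path; only clamping to the matrix bounds is needed.
expand_window <- function(path, n, m, radius) {
  ci <- path[, 1]; cj <- path[, 2]
  # ci and cj are nondecreasing along the path, so per coarse row the
  # column extremes come from its first and last path cell
  first <- which(c(TRUE, diff(ci) > 0))
  last <- c(first[-1] - 1L, length(ci))
  lo0 <- rep(2 * cj[first] - 1, each = 2)[seq_len(n)]
  hi0 <- rep(2 * cj[last], each = 2)[seq_len(n)]
  # inflate by `radius` along rows (sliding min/max over 2*radius+1 rows)
  lo <- lo0; hi <- hi0
  if (radius > 0) {
    for (s in seq_len(radius)) {
      lo <- pmin(lo, c(lo0[-seq_len(s)], rep(Inf, s)),
                 c(rep(Inf, s), lo0[seq_len(n - s)]))
      hi <- pmax(hi, c(hi0[-seq_len(s)], rep(-Inf, s)),
                 c(rep(-Inf, s), hi0[seq_len(n - s)]))
    }
  }
  # ...and along columns
  lo <- pmax(lo - radius, 1L)
  hi <- pmin(hi + radius, m)
  list(jmin = as.integer(pmin(lo, m)), jmax = as.integer(pmax(hi, 1L)))
}

#' Pairwise DTW distance matrix
#'
#' @param seqs list of point sequences (or trajectories).
#' @param method `"exact"` for full dynamic programming, `"fast"` for the
#'   multilevel approximation.
#' @param radius band radius for `method = "fast"`.
#' @return Symmetric matrix with zero diagonal.
#' @export
pairwise_dtwd <- function(seqs, method = c("exact", "fast"), radius = 1L) {
  method <- match.arg(method)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  xs <- lapply(seqs, as_xy)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- if (method == "exact") dtw_distance(xs[[i]], xs[[j]])
         else fast_dtw_distance(xs[[i]], xs[[j]], radius)
    D[i, j] <- d; D[j, i] <- d
  }
  dimnames(D) <- list(names(seqs), names(seqs))
  D
}
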