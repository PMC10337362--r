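#' Tablet trajectory objects
#'
#' A trajectory is the ordered stream of samples recorded by the digitizing
#' tablet while a subject completes one block of the Shape Trail Test: for
#' each sample an `x` / `y` position in device units, a pen `pressure`
#' (device units, `0` meaning the pen is lifted off the paper), and a
#' timestamp `t` in seconds. The tablet's active area maps the A4 sheet to
#' `x` in `[0, 21000]` and `y` in `[0, 29700]` (100 device units per mm).
#'
#' `trajectory()` validates and normalises a sample stream. In `"strict"`
#' mode out-of-range coordinates, negative pressures or non-increasing
#' timestamps are errors; in `"lenient"` mode coordinates are clamped to the
#' tablet bounds, negative pressures are set to zero, and a warning is
#' raised. Samples sharing a timestamp with their predecessor are dropped
#' (the first is kept) in both modes, because downstream derivatives need
#' strictly increasing times.
#'
#' @param x,y numeric sample coordinates (device units).
#' @param pressure numeric pen pressure, `>= 0`; exactly `0` iff pen lifted.
#' @param t numeric timestamps in seconds, strictly increasing after
#'   duplicate collapsing.
#' @param subject_id character scalar identifier.
#' @param part `"A"` or `"B"`.
#' @param block `1` (warm-up, targets 1-8) or `2` (scored, targets 1-25).
#' @param mode `"strict"` or `"lenient"` validation.
#' @return An object of class `tmt_trajectory`: a data frame with columns
#'   `x`, `y`, `pressure`, `t` and attributes `subject_id`, `part`, `block`.
#' @examples
#' tr <- trajectory(x = c(100, 200, 300), y = c(50, 60, 70),
#'                  pressure = c(800, 900, 0), t = c(0, 0.02, 0.04),
#'                  subject_id = "s1", part = "A", block = 2)
#' completion_time(tr)
#' @export
trajectory <- function(x, y, pressure, t, subject_id = "anon",
                       part = c("A", "B"), block = c(1L, 2L),
                       mode = c("strict", "lenient")) {
  part <- match.arg(as.character(part), c("A", "B"))
  block <- as.integer(block)[1]
  if (!block %in% c(1L, 2L)) stop("`block` must be 1 or 2")
  mode <- match.arg(mode)
  n <- length(x)
  if (length(y) != n || length(pressure) != n || length(t) != n)
    stop("x, y, pressure and t must have equal length")
  if (n < 2L) stop("a trajectory needs at least 2 samples")
  x <- as.numeric(x); y <- as.numeric(y)
  pressure <- as.numeric(pressure); t <- as.numeric(t)
  if (anyNA(x) || anyNA(y) || anyNA(pressure) || anyNA(t))
    stop("trajectory samples must not contain missing values")

  bad_xy <- x < 0 | x > TABLET_XMAX | y < 0 | y > TABLET_YMAX
  bad_p <- pressure < 0
  if (mode == "strict") {
    if (any(bad_xy))
      stop("sample(s) ", paste(head(which(bad_xy), 5), collapse = ", "),
           " outside tablet bounds [0,", TABLET_XMAX, "] x [0,", TABLET_YMAX, "]")
    if (any(bad_p))
      stop("negative pressure at sample(s) ",
           paste(head(which(bad_p), 5), collapse = ", "))
    if (any(diff(t) < 0))
      stop("timestamps decrease at sample(s) ",
           paste(head(which(diff(t) < 0) + 1L, 5), collapse = ", "))
  } else {
    if (any(bad_xy)) {
      warning(sum(bad_xy), " sample(s) clamped to tablet bounds")
      x <- pmin(pmax(x, 0), TABLET_XMAX)
      y <- pmin(pmax(y, 0), TABLET_YMAX)
    }
    if (any(bad_p)) {
      warning(sum(bad_p), " negative pressure(s) set to 0")
      pressure[bad_p] <- 0
    }
    ord <- order(t)
    x <- x[ord]; y <- y[ord]; pressure <- pressure[ord]; t <- t[ord]
  }
  dup <- c(FALSE, diff(t) == 0)
  if (any(dup)) {
    x <- x[!dup]; y <- y[!dup]; pressure <- pressure[!dup]; t <- t[!dup]
  }
  if (length(t) < 2L) stop("fewer than 2 samples remain after collapsing duplicate timestamps")

  out <- data.frame(x = x, y = y, pressure = pressure, t = t)
  structure(out, class = c("tmt_trajectory", "data.frame"),
            subject_id = as.character(subject_id), part = part, block = block)
}

TABLET_XMAX <- 21000
TABLET_YMAX <- 29700

#' @export
print.tmt_trajectory <- function(x, ...) {
  cat(sprintf("<tmt_trajectory> subject %s, part %s block %d: %d samples, %.2f s, %.0f%% pen-down\n",
              attr(x, "subject_id"), attr(x, "part"), attr(x, "block"),
              nrow(x), x$t[nrow(x)] - x$t[1], 100 * mean(x$pressure > 0)))
  invisible(x)
}

is_trajectory <- function(x) inherits(x, "tmt_trajectory")

traj_key <- function(traj) paste0(attr(traj, "part"), attr(traj, "block"))

#' Segment a trajectory into pen-down strokes
#'
#' A stroke is a maximal run of consecutive samples with `pressure > 0`;
#' pen-up samples (pressure exactly zero, the tablet sensing the hovering
#' pen) separate strokes and belong to none. Every pen-down sample belongs
#' to exactly one stroke.
#'
#' @param traj a [trajectory()].
#' @return A list of data frames (columns `x`, `y`, `pressure`, `t`), each
#'   with attributes `start_t` and `end_t`; ordered by time. A trajectory
#'   with no pen-down sample yields an empty list.
#' @export
segment_strokes <- function(traj) {
  stopifnot(is_trajectory(traj))
  down <- traj$pressure > 0
  if (!any(down)) return(list())
  r <- rle(down)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    s <- as.data.frame(traj)[idx, , drop = FALSE]
    rownames(s) <- NULL
    attr(s, "start_t") <- s$t[1]
    attr(s, "end_t") <- s$t[nrow(s)]
    s
  })
}

#' Subject records
#'
#' Bundles the (up to four) block trajectories of one subject with optional
#' clinical metadata: diagnostic group (`HC`, `MCI`, `AD`), sex, age,
#' education years, and the examiner's interaction counts for the scored
#' blocks (connection errors, prompts, pen-up warnings).
#'
#' @param subject_id character scalar.
#' @param trajectories named list of [trajectory()] objects; names must be
#'   among `"A1"`, `"A2"`, `"B1"`, `"B2"` (at most one per block).
#' @param group optional `"HC"`, `"MCI"` or `"AD"`.
#' @param sex optional `"F"`/`"M"`; age, education optional numerics (years).
#' @param age,education optional numerics (years).
#' @param interaction_counts optional named numeric vector with names among
#'   `errors_A2`, `errors_B2`, `penup_warnings_A2`, `penup_warnings_B2`,
#'   `prompts_A2`, `prompts_B2`; nonnegative integers.
#' @return An object of class `tmt_subject`.
#' @export
subject_record <- function(subject_id, trajectories = list(), group = NULL,
                           sex = NULL, age = NULL, education = NULL,
                           interaction_counts = NULL) {
  keys <- c("A1", "A2", "B1", "B2")
  if (length(trajectories)) {
    if (is.null(names(trajectories)) || !all(names(trajectories) %in% keys))
      stop("trajectory names must be among ", paste(keys, collapse = ", "))
    if (anyDuplicated(names(trajectories)))
      stop("at most one trajectory per (part, block)")
    ok <- vapply(trajectories, is_trajectory, logical(1))
    if (!all(ok)) stop("all elements of `trajectories` must be trajectory objects")
  }
  if (!is.null(group)) group <- match.arg(group, c("HC", "MCI", "AD"))
  if (!is.null(interaction_counts)) {
    allowed <- c("errors_A2", "errors_B2", "penup_warnings_A2",
                 "penup_warnings_B2", "prompts_A2", "prompts_B2")
    if (!all(names(interaction_counts) %in% allowed))
      stop("unknown interaction count name")
    if (any(interaction_counts < 0)) stop("interaction counts must be nonnegative")
  }
  structure(list(subject_id = as.character(subject_id), group = group,
                 sex = sex, age = age, education = education,
                 trajectories = trajectories,
                 interaction_counts = interaction_counts),
            class = "tmt_subject")
}

#' @export
print.tmt_subject <- function(x, ...) {
  cat(sprintf("<tmt_subject> %s (%s): blocks %s\n", x$subject_id,
              if (is.null(x$group)) "unlabelled" else x$group,
              paste(names(x$trajectories), collapse = " ")))
  invisible(x)
}
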