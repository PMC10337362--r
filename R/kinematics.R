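#' Time-related block features
#'
#' `completion_time()` is the elapsed time of the block, last timestamp
#' minus first. `pen_state_durations()` splits it into execution time (total
#' pen-down time: the sum of inter-sample intervals whose earlier sample has
#' positive pressure) and preparation — or "thinking" — time (total pen-up
#' time, `completion - execution`). The zero-pressure convention of the
#' tablet makes this split well defined.
#'
#' @param traj a [trajectory()].
#' @return `completion_time()`: seconds. `pen_state_durations()`: named
#'   numeric `c(preparation=, execution=)` in seconds.
#' @export
completion_time <- function(traj) {
  stopifnot(is_trajectory(traj))
  traj$t[nrow(traj)] - traj$t[1]
}

#' @rdname completion_time
#' @export
pen_state_durations <- function(traj) {
  stopifnot(is_trajectory(traj))
  n <- nrow(traj)
  dt <- diff(traj$t)
  down <- traj$pressure[-n] > 0
  execution <- sum(dt[down])
  total <- traj$t[n] - traj$t[1]
  if (!any(traj$pressure > 0))
    warning("trajectory has no pen-down samples; execution time is 0")
  c(preparation = total - execution, execution = execution)
}

#' Cross-block completion-time contrasts
#'
#' Part B of the test demands set shifting between circles and squares, so
#' the contrast between the scored blocks of parts A and B indexes cognitive
#' flexibility. `time_difference()` is `tA2 - tB2` (negative when part B
#' takes longer, as in healthy controls). `time_ratio()` is `tA2 / tB2`,
#' with the convention that a zero denominator (a block coded as failed) is
#' replaced by `-1`, so the result is `-tA2`.
#'
#' @param tA2,tB2 completion times (seconds) of blocks A-2 and B-2.
#' @return A scalar; `time_ratio()` carries attribute
#'   `zero_denominator = TRUE` when the replacement rule fired.
#' @export
time_difference <- function(tA2, tB2) {
  stopifnot(is.finite(tA2), is.finite(tB2))
  tA2 - tB2
}

#' @rdname time_difference
#' @export
time_ratio <- function(tA2, tB2) {
  stopifnot(is.finite(tA2), is.finite(tB2))
  if (tB2 == 0) structure(tA2 / -1, zero_denominator = TRUE)
  else tA2 / tB2
}

#' Writing-pressure summary
#'
#' Mean, minimum and maximum pen pressure over the pen-down samples of a
#' block. Pen-up samples (pressure zero) are excluded: the features describe
#' writing pressure, and including lifts would force every minimum to zero.
#'
#' @param traj a [trajectory()].
#' @return Named numeric `c(mean=, min=, max=)` in device pressure units,
#'   or all-`NA` when the trajectory has no pen-down sample.
#' @export
pressure_summary <- function(traj) {
  stopifnot(is_trajectory(traj))
  p <- traj$pressure[traj$pressure > 0]
  if (!length(p)) return(c(mean = NA_real_, min = NA_real_, max = NA_real_))
  c(mean = mean(p), min = min(p), max = max(p))
}

#' Jerk smoothness metric
#'
#' Jerk is the third time-derivative of pen position; skilled smooth
#' movement minimises it, while tremor and ataxic corrections inflate it.
#' For each pen-down stroke the x/y positions are resampled onto a uniform
#' time grid at the trajectory's median sampling interval (linear
#' interpolation), the third derivative is estimated by central finite
#' differences, and the stroke's jerk is the root mean square of the jerk
#' vector magnitude. Strokes with fewer than 5 resampled points cannot
#' support a third difference and are skipped; eligible strokes are
#' aggregated by a duration-weighted mean.
#'
#' @param traj a [trajectory()].
#' @return Nonnegative scalar in device units per second cubed, or `NA`
#'   when no stroke is eligible.
#' @export
jerk_metric <- function(traj) {
  stopifnot(is_trajectory(traj))
  strokes <- segment_strokes(traj)
  if (!length(strokes)) return(NA_real_)
  h <- median(diff(traj$t))
  if (!is.finite(h) || h <= 0) return(NA_real_)
  vals <- numeric(0); wts <- numeric(0)
  for (s in strokes) {
    dur <- s$t[nrow(s)] - s$t[1]
    grid <- seq(s$t[1], s$t[nrow(s)], by = h)
    if (length(grid) < 5L) next
    xs <- approx(s$t, s$x, xout = grid)$y
    ys <- approx(s$t, s$y, xout = grid)$y
    jx <- third_diff(xs, h)
    jy <- third_diff(ys, h)
    vals <- c(vals, sqrt(mean(jx^2 + jy^2)))
    wts <- c(wts, dur)
  }
  if (!length(vals)) return(NA_real_)
  sum(vals * wts) / sum(wts)
}

# central third difference: f'''(i) ~ (f[i+2]-2f[i+1]+2f[i-1]-f[i-2])/(2h^3)
third_diff <- function(f, h) {
  n <- length(f)
  i <- 3:(n - 2)
  (f[i + 2] - 2 * f[i + 1] + 2 * f[i - 1] - f[i - 2]) / (2 * h^3)
}

#' All kinematic features of one block
#'
#' Bundles [completion_time()], [pen_state_durations()],
#' [pressure_summary()] and [jerk_metric()]. Features that are undefined
#' for the input (e.g. pressure statistics of an all-pen-up trajectory) are
#' `NA` and propagate as missing values into the feature table.
#'
#' @param traj a [trajectory()].
#' @return Named numeric: `completion`, `prep`, `exec`, `pmean`, `pmin`,
#'   `pmax`, `jerk`.
#' @export
block_features <- function(traj) {
  ct <- completion_time(traj)
  pd <- suppressWarnings(pen_state_durations(traj))
  ps <- pressure_summary(traj)
  c(completion = ct, prep = unname(pd["preparation"]),
    exec = unname(pd["execution"]), pmean = unname(ps["mean"]),
    pmin = unname(ps["min"]), pmax = unname(ps["max"]),
    jerk = jerk_metric(traj))
}
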