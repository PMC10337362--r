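#' Generate a Shape Trail Test sheet layout
#'
#' Places the numbered targets of one test block inside the tablet's active
#' area (margins respected, centers rejection-sampled so that no two
#' targets overlap). Block 1 is the warm-up with numbers 1-8; block 2 is
#' the scored block with numbers 1-25. Part A shows each number once
#' (circles, visited in ascending order). Part B shows every number twice —
#' once in a circle and once in a square — except number 1, which appears
#' only inside a square; the prescribed path alternates enclosing shapes,
#' anchored at the square 1 (odd numbers in squares, even numbers in
#' circles), and the unvisited duplicates act as distractors.
#'
#' @param part `"A"` or `"B"`.
#' @param block `1` or `2`.
#' @param seed integer seed for target placement.
#' @param radius target radius in device units (500 = 5 mm on the sheet).
#' @return A `tmt_layout`: list with `part`, `block`, `targets` (data frame
#'   `label`, `shape`, `cx`, `cy`, `radius`) and `visiting_order` (row
#'   indices into `targets`).
#' @export
make_sheet_layout <- function(part = c("A", "B"), block = c(1L, 2L),
                              seed = 1L, radius = 500) {
  part <- match.arg(as.character(part), c("A", "B"))
  block <- as.integer(block)[1]
  stopifnot(block %in% c(1L, 2L))
  n_labels <- if (block == 1L) 8L else 25L
  if (part == "A") {
    labels <- seq_len(n_labels)
    shapes <- rep("circle", n_labels)
  } else {
    labels <- c(1L, rep(2:n_labels, each = 2L))
    shapes <- c("square", rep(c("circle", "square"), n_labels - 1L))
  }
  n <- length(labels)
  margin <- 2000
  local_seed(seed, {
    r <- radius
    for (shrink in 1:5) {
      pts <- place_targets(n, r, margin)
      if (!is.null(pts)) break
      r <- r * 0.8
    }
    if (is.null(pts)) stop("could not place ", n, " non-overlapping targets")
    targets <- data.frame(label = labels, shape = shapes,
                          cx = pts[, 1], cy = pts[, 2], radius = r)
    # visited target for each number: part A any (unique); part B the shape
    # dictated by the alternation rule
    visiting <- vapply(seq_len(n_labels), function(lab) {
      if (part == "A") which(targets$label == lab)
      else {
        want <- if (lab %% 2L == 1L) "square" else "circle"
        which(targets$label == lab & targets$shape == want)
      }
    }, integer(1))
    structure(list(part = part, block = block, targets = targets,
                   visiting_order = visiting),
              class = "tmt_layout")
  })
}

place_targets <- function(n, radius, margin) {
  max_attempts <- 400L * n
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L
  min_d2 <- (2.2 * radius)^2
  while (length(xs) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cx <- runif(1, margin, TABLET_XMAX - margin)
    cy <- runif(1, margin, TABLET_YMAX - margin)
    if (!length(xs) || all((xs - cx)^2 + (ys - cy)^2 > min_d2)) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  if (length(xs) < n) NULL else cbind(xs, ys)
}

#' @export
print.tmt_layout <- function(x, ...) {
  cat(sprintf("<tmt_layout> part %s block %d: %d targets, path of %d\n",
              x$part, x$block, nrow(x$targets), length(x$visiting_order)))
  invisible(x)
}

#' Group profiles for the trajectory simulator
#'
#' A profile parameterises how a diagnostic group draws: segment movement
#' speed (device units/s), the pen-up dwell ("thinking" pause) before each
#' target (mean and SD in seconds), writing pressure (mean and SD in device
#' units, sampled per pen-down sample), sinusoidal tremor superimposed on
#' the minimum-jerk path (amplitude in device units, frequency in Hz), the
#' tablet sampling rate (Hz), and the probability of an attentional lapse
#' (an extra long pause before a target).
#'
#' The shipped defaults encode the qualitative clinical ordering — slower
#' movement, longer and more variable pauses, lower and less stable
#' pressure, larger tremor, and more lapses with increasing impairment —
#' with magnitudes anchored to the published group-level completion,
#' preparation and pressure statistics of the scored blocks. They define
#' group *directions*, not a reproduction of any cohort's numbers.
#'
#' @param move_speed_mean,pause_mean,pause_sd,pressure_mean,pressure_sd
#'   see description.
#' @param tremor_amplitude,tremor_freq,sample_rate,lapse_prob see
#'   description.
#' @return `group_profile()`: a `tmt_profile` list.
#'   `default_group_profiles()`: named list with elements `HC`, `MCI`,
#'   `AD`.
#' @export
group_profile <- function(move_speed_mean = 3600, pause_mean = 0.1,
                          pause_sd = 0.05, pressure_mean = 1600,
                          pressure_sd = 150, tremor_amplitude = 10,
                          tremor_freq = 6, sample_rate = 100,
                          lapse_prob = 0.02) {
  stopifnot(move_speed_mean > 0, pause_mean >= 0, pause_sd >= 0,
            pressure_mean > 0, pressure_sd >= 0, tremor_amplitude >= 0,
            tremor_freq >= 0, sample_rate > 0,
            lapse_prob >= 0, lapse_prob <= 1)
  structure(as.list(environment()), class = "tmt_profile")
}

#' @rdname group_profile
#' @export
default_group_profiles <- function() {
  list(
    HC = group_profile(move_speed_mean = 3600, pause_mean = 0.05,
                       pause_sd = 0.03, pressure_mean = 1680,
                       pressure_sd = 140, tremor_amplitude = 10,
                       tremor_freq = 6, sample_rate = 100, lapse_prob = 0.02),
    MCI = group_profile(move_speed_mean = 2700, pause_mean = 0.13,
                        pause_sd = 0.08, pressure_mean = 1410,
                        pressure_sd = 160, tremor_amplitude = 25,
                        tremor_freq = 6, sample_rate = 100, lapse_prob = 0.08),
    AD = group_profile(move_speed_mean = 2200, pause_mean = 0.45,
                       pause_sd = 0.25, pressure_mean = 1010,
                       pressure_sd = 180, tremor_amplitude = 40,
                       tremor_freq = 6, sample_rate = 100, lapse_prob = 0.20))
}

#' Simulate one pen trajectory over a sheet layout
#'
#' For each consecutive pair of the layout's visiting order the simulated
#' pen optionally dwells pen-up at the current target (truncated-normal
#' pause, plus an occasional lapse), then draws a minimum-jerk segment to
#' the next target with sinusoidal tremor superimposed; pressure is sampled
#' per pen-down sample from a truncated normal. All event durations are
#' quantised to the sampling grid, so pen-state transitions coincide with
#' sample boundaries and the returned ground truth (total duration, total
#' pause and draw time, ideal tremor-free path) is exact at the sample
#' level.
#'
#' @param layout a [make_sheet_layout()] result.
#' @param profile a [group_profile()].
#' @param seed integer seed.
#' @param subject_id id stamped on the trajectory.
#' @return List with `trajectory` (a [trajectory()]) and `ground_truth`
#'   (list: `duration`, `pause_time`, `move_time`, `n_samples`,
#'   `path_length`, `ideal` data frame of the noiseless pen-down path).
#' @export
simulate_trajectory <- function(layout, profile, seed = 1L,
                                subject_id = "sim") {
  stopifnot(inherits(layout, "tmt_layout"), inherits(profile, "tmt_profile"))
  dt <- 1 / profile$sample_rate
  ord <- layout$visiting_order
  tg <- layout$targets[ord, , drop = FALSE]
  local_seed(seed, {
    # event list: alternating (pause?, move) per segment, durations in steps
    state <- character(0)  # "pause" / "move" per step
    px <- numeric(0); py <- numeric(0)          # sampled (tremor) path
    ix <- numeric(0); iy <- numeric(0)          # ideal path
    cur <- c(tg$cx[1], tg$cy[1])
    path_length <- 0
    for (s in seq_len(nrow(tg) - 1L)) {
      nxt <- c(tg$cx[s + 1L], tg$cy[s + 1L])
      pause <- rtruncnorm(1, profile$pause_mean, profile$pause_sd, lo = 0)
      if (runif(1) < profile$lapse_prob)
        pause <- pause + rtruncnorm(1, 2, 0.5, lo = 0.5)
      n_pause <- round(pause / dt)
      if (n_pause > 0) {
        state <- c(state, rep("pause", n_pause))
        px <- c(px, rep(cur[1], n_pause)); py <- c(py, rep(cur[2], n_pause))
        ix <- c(ix, rep(NA_real_, n_pause)); iy <- c(iy, rep(NA_real_, n_pause))
      }
      dist <- sqrt(sum((nxt - cur)^2))
      n_move <- max(4L, round(dist / profile$move_speed_mean / dt))
      tau <- (seq_len(n_move) - 1L) / n_move
      shape <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5   # minimum-jerk profile
      mx <- cur[1] + (nxt[1] - cur[1]) * shape
      my <- cur[2] + (nxt[2] - cur[2]) * shape
      tx <- mx; ty <- my
      if (profile$tremor_amplitude > 0) {
        tt <- (length(state) + seq_len(n_move) - 1L) * dt
        phx <- runif(1, 0, 2 * pi); phy <- runif(1, 0, 2 * pi)
        tx <- mx + profile$tremor_amplitude *
          sin(2 * pi * profile$tremor_freq * tt + phx)
        ty <- my + profile$tremor_amplitude *
          sin(2 * pi * profile$tremor_freq * tt + phy)
      }
      state <- c(state, rep("move", n_move))
      px <- c(px, tx); py <- c(py, ty)
      ix <- c(ix, mx); iy <- c(iy, my)
      path_length <- path_length + dist
      cur <- nxt
    }
    # terminal sample at the final target
    n_steps <- length(state)
    times <- c(seq_len(n_steps) - 1L, n_steps) * dt
    px <- c(px, cur[1]); py <- c(py, cur[2])
    ix <- c(ix, cur[1]); iy <- c(iy, cur[2])
    down <- c(state == "move", TRUE)
    pressure <- numeric(n_steps + 1L)
    pressure[down] <- rtruncnorm(sum(down), profile$pressure_mean,
                                 profile$pressure_sd, lo = 1)
    px <- pmin(pmax(px, 0), TABLET_XMAX)
    py <- pmin(pmax(py, 0), TABLET_YMAX)
    traj <- trajectory(px, py, pressure, times, subject_id = subject_id,
                       part = layout$part, block = layout$block)
    gt <- list(duration = n_steps * dt,
               pause_time = sum(state == "pause") * dt,
               move_time = sum(state == "move") * dt,
               n_samples = n_steps + 1L,
               path_length = path_length,
               ideal = data.frame(t = times, x = ix, y = iy))
    list(trajectory = traj, ground_truth = gt)
  })
}

#' Simulate a labelled synthetic cohort
#'
#' Draws `n_per_group` subjects per diagnostic group. All subjects share
#' one sheet layout per (part, block) — as with a printed test form — and
#' each subject receives multiplicative log-normal random effects on speed
#' and pause duration and an additive normal effect on pressure, so
#' within-group variation exists on top of the group profiles. Demographics
#' (sex, age, education) are sampled with group-level shifts matching the
#' usual clinical pattern (older, less educated with impairment). Examiner
#' interaction counts are all zero unless `simulate_interactions = TRUE`,
#' in which case they are Poisson draws with group-dependent means (the
#' drawn trace itself never contains errors).
#'
#' @param n_per_group named integer vector, e.g. `c(HC = 20, MCI = 20, AD = 20)`.
#' @param profiles named list of [group_profile()]s covering those groups.
#' @param seed integer master seed; everything (layouts, subjects,
#'   trajectories) is derived from it.
#' @param simulate_interactions logical; see above.
#' @return A `tmt_cohort`: list with `records` (list of
#'   [subject_record()]), `ground_truth` (data frame, one row per subject x
#'   block), `layouts` (named list), `seed`.
#' @export
simulate_cohort <- function(n_per_group = c(HC = 20L, MCI = 20L, AD = 20L),
                            profiles = default_group_profiles(),
                            seed = 1L, simulate_interactions = FALSE) {
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% names(profiles)))
    stop("`profiles` must provide an entry for every group in `n_per_group`")
  blocks <- list(A1 = c("A", 1L), A2 = c("A", 2L),
                 B1 = c("B", 1L), B2 = c("B", 2L))
  layouts <- lapply(names(blocks), function(key)
    make_sheet_layout(blocks[[key]][1], as.integer(blocks[[key]][2]),
                      seed = derive_seed(seed, "layout", key)))
  names(layouts) <- names(blocks)

  # mean interaction counts per group, used only when simulate_interactions
  ic_means <- list(
    HC = c(errors_A2 = 0.04, errors_B2 = 0.43, penup_warnings_A2 = 0.68,
           penup_warnings_B2 = 0.98, prompts_A2 = 0.06, prompts_B2 = 1.42),
    MCI = c(errors_A2 = 0.14, errors_B2 = 1.07, penup_warnings_A2 = 1.21,
            penup_warnings_B2 = 1.63, prompts_A2 = 0.28, prompts_B2 = 2.96),
    AD = c(errors_A2 = 0.27, errors_B2 = 0.55, penup_warnings_A2 = 2.56,
           penup_warnings_B2 = 1.54, prompts_A2 = 1.49, prompts_B2 = 2.75))

  records <- list()
  gt_rows <- list()
  for (g in groups) {
    base <- profiles[[g]]
    for (i in seq_len(n_per_group[[g]])) {
      sid <- sprintf("%s%03d", g, i)
      sseed <- derive_seed(seed, "subject", g, i)
      meta <- local_seed(sseed, {
        list(speed_mult = exp(rnorm(1, 0, 0.08)),
             pause_mult = exp(rnorm(1, 0, 0.15)),
             pressure_shift = rnorm(1, 0, 60),
             sex = sample(c("F", "M"), 1),
             age = round(rtruncnorm(1, 70 + 2 * (g != "HC"), 7, lo = 50, hi = 95)),
             education = round(rtruncnorm(
               1, c(HC = 12.5, MCI = 10, AD = 8.5)[[g]] %||% 12, 3.5,
               lo = 0, hi = 22)),
             counts = if (simulate_interactions && g %in% names(ic_means))
               vapply(ic_means[[g]], function(m) stats::rpois(1, m), numeric(1))
             else setNames(rep(0, 6), names(ic_means[[1]])))
      })
      prof <- base
      prof$move_speed_mean <- base$move_speed_mean * meta$speed_mult
      prof$pause_mean <- base$pause_mean * meta$pause_mult
      prof$pressure_mean <- max(200, base$pressure_mean + meta$pressure_shift)
      trajs <- list()
      for (key in names(layouts)) {
        sim <- simulate_trajectory(layouts[[key]], prof,
                                   seed = derive_seed(sseed, "traj", key),
                                   subject_id = sid)
        trajs[[key]] <- sim$trajectory
        gt_rows[[length(gt_rows) + 1L]] <- data.frame(
          subject_id = sid, group = g, key = key,
          duration = sim$ground_truth$duration,
          pause_time = sim$ground_truth$pause_time,
          move_time = sim$ground_truth$move_time,
          n_samples = sim$ground_truth$n_samples,
          path_length = sim$ground_truth$path_length,
          pressure_mean = prof$pressure_mean,
          pressure_sd = prof$pressure_sd)
      }
      records[[length(records) + 1L]] <- subject_record(
        sid, trajectories = trajs, group = g, sex = meta$sex,
        age = meta$age, education = meta$education,
        interaction_counts = meta$counts)
    }
  }
  structure(list(records = records,
                 ground_truth = do.call(rbind, gt_rows),
                 layouts = layouts, seed = as.integer(seed)),
            class = "tmt_cohort")
}

#' @export
print.tmt_cohort <- function(x, ...) {
  grp <- table(vapply(x$records, function(r) r$group %||% "?", character(1)))
  cat("<tmt_cohort>", length(x$records), "subjects:",
      paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
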