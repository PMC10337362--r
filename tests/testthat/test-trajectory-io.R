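test_that("trajectory validation enforces tablet bounds and monotone time", {
  expect_error(make_traj(c(0, 22000), c(0, 0), c(1, 1), c(0, 1)),
               "tablet bounds")
  expect_error(make_traj(c(0, 1), c(0, 0), c(1, -2), c(0, 1)), "negative pressure")
  expect_error(make_traj(c(0, 1, 2), c(0, 0, 0), c(1, 1, 1), c(0, 2, 1)),
               "decrease")
  # lenient mode clamps and warns instead
  expect_warning(tr <- trajectory(c(0, 22000), c(0, 0), c(1, 1), c(0, 1),
                                  mode = "lenient"), "clamped")
  expect_equal(max(tr$x), 21000)
  # duplicate timestamps: first sample kept
  tr <- make_traj(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1), c(0, 0, 1))
  expect_equal(nrow(tr), 2)
  expect_equal(tr$x, c(1, 3))
})

test_that("stroke segmentation partitions pen-down samples", {
  tr <- make_traj(1:4, 1:4, c(5, 5, 0, 5), c(0, 1, 2, 3))
  s <- segment_strokes(tr)
  expect_length(s, 2)
  expect_equal(vapply(s, nrow, integer(1)), c(2L, 1L))

  tr <- make_traj(1:4, 1:4, c(5, 5, 5, 5), c(0, 1, 2, 3))
  expect_length(segment_strokes(tr), 1)
  expect_equal(nrow(segment_strokes(tr)[[1]]), 4)

  tr <- make_traj(1:10, 1:10, rep(c(0, 7), 5), 0:9)
  expect_length(segment_strokes(tr), 5)
  expect_true(all(vapply(segment_strokes(tr), nrow, integer(1)) == 1L))

  # all pen-up -> empty list
  tr <- make_traj(1:3, 1:3, c(0, 0, 0), 0:2)
  expect_length(segment_strokes(tr), 0)

  # partition property on simulated trajectories
  lay <- make_sheet_layout("A", 1, seed = 4)
  for (s0 in 1:3) {
    sim <- simulate_trajectory(lay, default_group_profiles()$MCI, seed = s0)
    strokes <- segment_strokes(sim$trajectory)
    expect_equal(sum(vapply(strokes, nrow, integer(1))),
                 sum(sim$trajectory$pressure > 0))
  }
})

test_that("delimited-samples files round-trip bit-identically", {
  coh <- simulate_cohort(c(HC = 2L, AD = 1L), seed = 21)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(coh$records, f)
  back <- read_trajectories(f)
  expect_length(back, 3)
  for (i in seq_along(back)) {
    orig <- coh$records[[i]]
    expect_equal(back[[i]]$subject_id, orig$subject_id)
    expect_setequal(names(back[[i]]$trajectories), names(orig$trajectories))
    for (key in names(orig$trajectories)) {
      a <- as.data.frame(orig$trajectories[[key]])
      b <- as.data.frame(back[[i]]$trajectories[[key]])
      expect_identical(a$x, b$x)
      expect_identical(a$t, b$t)
      expect_identical(a$pressure, b$pressure)
    }
  }
  # write(read(x)) == write-stable
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("structured-records dialect round-trips metadata", {
  coh <- simulate_cohort(c(HC = 1L, MCI = 1L), seed = 8,
                         simulate_interactions = TRUE)
  f <- withr::local_tempfile(fileext = ".json")
  write_trajectories(coh$records, f, dialect = "structured-records")
  back <- read_trajectories(f, dialect = "structured-records")
  orig <- coh$records[[2]]
  rec <- back[[2]]
  expect_equal(rec$group, "MCI")
  expect_equal(rec$age, orig$age)
  expect_equal(rec$education, orig$education)
  expect_equal(unname(rec$interaction_counts["prompts_B2"]),
               unname(orig$interaction_counts[["prompts_B2"]]))
  expect_identical(as.data.frame(rec$trajectories$B2),
                   as.data.frame(orig$trajectories$B2))
})

test_that("reader reports malformed input precisely", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,part,block,x,y,pressure,t",
               "s1,A,2,100,100,500,0.0",
               "s1,A,2,110,100,500,0.2",
               "s1,A,2,120,100,500,0.1"), f)
  expect_error(read_trajectories(f), "line 4")
  expect_silent(read_trajectories(f, mode = "lenient"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,part,block,x,y,t", "s1,A,2,1,1,0"), f2)
  expect_error(read_trajectories(f2), "pressure")

  # empty record list -> header-only file -> empty read
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(list(), f3)
  expect_equal(length(readLines(f3)), 1L)
  expect_length(read_trajectories(f3), 0)

  # 100-row single-subject file -> one record with a 100-sample trajectory
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,part,block,x,y,pressure,t",
               sprintf("s9,B,1,%d,%d,800,%.2f", 1:100, 1:100, (1:100) / 50)), f4)
  recs <- read_trajectories(f4)
  expect_length(recs, 1)
  expect_equal(nrow(recs[[1]]$trajectories$B1), 100)
})

test_that("time_unit converts device clocks to seconds", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,part,block,x,y,pressure,t",
               "s1,A,2,0,0,1,0", "s1,A,2,10,0,1,500", "s1,A,2,20,0,1,1000"), f)
  recs <- read_trajectories(f, time_unit = 1000)
  expect_equal(completion_time(recs[[1]]$trajectories$A2), 1.0)
})
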