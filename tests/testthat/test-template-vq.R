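test_that("gaussian_smooth is an identity at sigma 0 and on constant paths", {
  tr <- make_traj(c(1, 5, 2, 8), c(2, 2, 9, 1), rep(1, 4), 0:3)
  expect_identical(as.data.frame(gaussian_smooth(tr, 0)), as.data.frame(tr))
  const <- make_traj(rep(7, 10), rep(3, 10), rep(1, 10), 0:9)
  expect_equal(gaussian_smooth(const, 3)$x, rep(7, 10))
  expect_equal(gaussian_smooth(const, 3)$y, rep(3, 10))
})

test_that("gaussian_smooth matches a direct convolution oracle", {
  step <- c(rep(0, 12), rep(100, 13))
  tr <- make_traj(step, rev(step), rep(1, 25), 0:24)
  sm <- gaussian_smooth(tr, sigma = 2)
  expect_equal(sm$x, conv_oracle(step, 2))
  expect_equal(sm$y, conv_oracle(rev(step), 2))
  # pressure and time untouched
  expect_identical(sm$pressure, tr$pressure)
  expect_identical(sm$t, tr$t)
})

test_that("vq_cluster recovers closed-form solutions", {
  pts <- data.frame(x = c(1, 2, 6), y = c(1, 3, 2), t = 1:3)
  cl <- vq_cluster(pts, k = 1, seed = 1)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$center, c(3, 2))
  # k == n distinct points: centers are the points
  cl <- vq_cluster(pts, k = 3, seed = 1)
  centers <- do.call(rbind, lapply(cl, `[[`, "center"))
  expect_equal(centers[order(centers[, 1]), ],
               as.matrix(pts[order(pts$x), c("x", "y")]),
               ignore_attr = TRUE)
  # k capped at distinct-point count
  dup <- data.frame(x = c(1, 1, 5), y = c(1, 1, 5), t = 1:3)
  expect_lte(length(vq_cluster(dup, k = 10, seed = 2)), 2)
})

test_that("vq_cluster separates well-spaced blobs", {
  set.seed(4)
  b1 <- cbind(rnorm(40, 3000, 10), rnorm(40, 5000, 10))
  b2 <- cbind(rnorm(40, 5000, 10), rnorm(40, 5000, 10))
  pts <- data.frame(x = c(b1[, 1], b2[, 1]), y = c(b1[, 2], b2[, 2]),
                    t = seq_len(80))
  cl <- vq_cluster(pts, k = 2, seed = 9)
  centers <- do.call(rbind, lapply(cl, `[[`, "center"))
  centers <- centers[order(centers[, 1]), ]
  expect_lt(max(abs(centers[1, ] - colMeans(b1))), 3)
  expect_lt(max(abs(centers[2, ] - colMeans(b2))), 3)
})

test_that("temporal restructuring removes stray points and keeps order", {
  # hand-constructed 6-point example: cluster at mean t 3.0 holds a stray
  # point from t=0.5 that predates the first cluster's mean time 1.0
  cl <- list(
    list(points = data.frame(x = c(0, 0, 0), y = c(0, 0, 0),
                             t = c(0.5, 1.0, 1.5)),
         center = c(0, 0), mean_t = 1.0, n = 3L),
    list(points = data.frame(x = c(10, 10, 10), y = c(0, 0, 2),
                             t = c(0.5, 4.0, 4.5)),
         center = c(10, 2 / 3), mean_t = 3.0, n = 3L))
  kp <- temporal_restructure(cl)
  expect_equal(nrow(kp), 2)
  expect_equal(kp$cx, c(0, 10))
  expect_equal(kp$cy, c(0, 1))          # mean of surviving (0, 2)
  expect_equal(kp$mean_t, c(1.0, 4.25)) # stray t=0.5 dropped
  expect_equal(kp$n_points, c(3L, 2L))

  # temporally consistent clusters: nothing removed
  cl2 <- list(
    list(points = data.frame(x = 1:3, y = 1:3, t = c(1, 2, 3)),
         center = c(2, 2), mean_t = 2, n = 3L),
    list(points = data.frame(x = 4:6, y = 4:6, t = c(4, 5, 6)),
         center = c(5, 5), mean_t = 5, n = 3L))
  kp2 <- temporal_restructure(cl2)
  expect_equal(kp2$cx, c(2, 5))
  expect_equal(kp2$n_points, c(3L, 3L))

  # single cluster: no neighbours, unchanged
  kp3 <- temporal_restructure(cl2[1])
  expect_equal(kp3$cx, 2)
  expect_equal(kp3$n_points, 3L)
})

test_that("temporal restructuring agrees with an independent oracle", {
  for (s in 1:15) {
    cl <- random_clustering(n = 100, k = 5, seed = s)
    kp <- temporal_restructure(cl)
    orc <- restructure_oracle(cl)
    expect_equal(kp$cx, orc$cx)
    expect_equal(kp$mean_t, orc$mean_t)
    expect_equal(kp$n_points, orc$n_points)
    expect_true(all(diff(kp$mean_t) > 0))
  }
})

test_that("extract_keypoints finds dwell blobs and obeys its contracts", {
  # trajectory dwelling at 6 well-separated spots
  set.seed(2)
  spots <- cbind(seq(2000, 18000, length.out = 6),
                 seq(3000, 25000, length.out = 6))
  x <- c(); y <- c(); t <- c()
  for (i in 1:6) {
    x <- c(x, spots[i, 1] + rnorm(30, 0, 20))
    y <- c(y, spots[i, 2] + rnorm(30, 0, 20))
    t <- c(t, (i - 1) * 3 + seq(0, 2.9, length.out = 30))
  }
  tr <- make_traj(x, y, rep(900, length(x)), t)
  kp <- extract_keypoints(tr, k = 6, seed = 3)
  expect_equal(nrow(kp), 6)
  expect_lt(max(abs(sort(kp$cx) - spots[, 1])), 25)
  expect_true(all(diff(kp$mean_t) > 0))
  expect_lte(sum(kp$weight), 1 + 1e-12)
  expect_equal(sum(kp$weight), 1)  # nothing removed for dwell data

  # determinism and count bound on a simulated trace
  sim <- simulate_trajectory(make_sheet_layout("A", 1, seed = 2),
                             default_group_profiles()$HC, seed = 5)
  k1 <- extract_keypoints(sim$trajectory, seed = 7)
  k2 <- extract_keypoints(sim$trajectory, seed = 7)
  expect_identical(as.data.frame(k1), as.data.frame(k2))
  expect_lte(nrow(k1), 40)
  expect_true(all(diff(k1$mean_t) > 0))
})

test_that("select_template picks the centroid-like trajectory", {
  base <- cbind(seq(1000, 9000, length.out = 20), rep(5000, 20))
  mk <- function(dx, sid) make_traj(base[, 1] + dx, base[, 2],
                                    rep(1, 20), seq(0, 1.9, by = 0.1),
                                    sid = sid)
  pool <- list(mk(0, "a"), mk(1, "b"), mk(10, "c"))
  # the middle trajectory minimises summed DTWD
  sel <- select_template(pool, subset_size = 3, seed = 1)
  expect_equal(attr(sel, "subject_id"), "b")
  # pool of one
  expect_equal(attr(select_template(pool[1]), "subject_id"), "a")
  # tie between identical twins: lowest subject id wins
  pool2 <- list(mk(0, "z"), mk(0, "q"), mk(500, "m"))
  sel2 <- select_template(pool2, subset_size = 3, seed = 2)
  expect_equal(attr(sel2, "subject_id"), "q")
})

test_that("template_features satisfies its closed-form identities", {
  kp <- structure(data.frame(idx = 1:3, cx = c(0, 10, 20), cy = c(0, 0, 0),
                             mean_t = 1:3, n_points = c(5L, 3L, 2L),
                             weight = c(0.5, 0.3, 0.2)),
                  class = c("tmt_keypoints", "data.frame"))
  expect_equal(template_features(kp, kp),
               c(dtwd = 0, vq_unweighted = 0, vq_weighted = 0))
  # translation perpendicular to the center sequence, equal weights: index
  # pairing and the DTW diagonal are both forced, so all three are d-scaled
  kpe <- kp; kpe$weight <- rep(1 / 3, 3)
  ref <- kpe; ref$cy <- ref$cy + 7
  tf <- template_features(ref, kpe)
  expect_equal(unname(tf["vq_unweighted"]), 7)
  expect_equal(unname(tf["vq_weighted"]), 7)
  expect_equal(unname(tf["dtwd"]), 3 * 7)
  # hand-computed weighted example: distances (10, 20, 30), weights (.5,.3,.2)
  ref2 <- kp; ref2$cy <- kp$cy + c(10, 20, 30)
  tf2 <- template_features(ref2, kp)
  expect_equal(unname(tf2["vq_unweighted"]), 20)
  expect_equal(unname(tf2["vq_weighted"]), 17)
  # unequal lengths pair up to the shorter sequence
  tf3 <- template_features(ref2[1:2, ], kp)
  expect_equal(unname(tf3["vq_unweighted"]), 15)
})

test_that("template archives reload losslessly", {
  sim <- simulate_trajectory(make_sheet_layout("B", 1, seed = 3),
                             default_group_profiles()$HC, seed = 4,
                             subject_id = "ref1")
  kp <- extract_keypoints(sim$trajectory, seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_templates(list(B1 = kp), f)
  back <- read_templates(f)
  expect_equal(back$B1$cx, kp$cx)
  expect_equal(back$B1$weight, kp$weight)
  expect_equal(attr(back$B1, "subject_id"), "ref1")
  expect_equal(attr(back$B1, "k"), 40L)
  # features against a reloaded template are unchanged
  expect_equal(template_features(back$B1, kp),
               template_features(kp, kp))
})
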