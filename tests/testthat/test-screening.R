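make_small_cohort <- function(seed = 31, n = c(HC = 6L, MCI = 4L, AD = 4L)) {
  simulate_cohort(n, seed = seed)
}

test_that("feature sets contain exactly the advertised columns", {
  coh <- make_small_cohort(seed = 41, n = c(HC = 3L, MCI = 2L, AD = 2L))
  kp <- cohort_keypoints(coh, seed = 41)
  tpl <- fit_templates(coh, subset_size = 3, seed = 41, method = "fast",
                       keypoints = kp)

  conv <- assemble_feature_table(coh, feature_set = "conventional")
  expect_setequal(setdiff(names(conv), c("subject_id", "label")),
                  c("completion_A1", "completion_A2", "completion_B1",
                    "completion_B2", "sex", "age", "education",
                    "errors_A2", "errors_B2", "penup_warnings_A2",
                    "penup_warnings_B2", "prompts_A2", "prompts_B2"))

  prop <- assemble_feature_table(coh, templates = tpl, feature_set = "proposed",
                                 keypoints = kp)
  feats <- setdiff(names(prop), c("subject_id", "label"))
  expect_false(any(grepl("errors|warnings|prompts", feats)))
  expect_true(all(c("jerk_B2", "tmpl_dtwd_A2", "tmpl_vq_B1", "tmpl_vqw_B2",
                    "tdiff_A2B2", "tratio_A2B2", "pmin_A1", "sex") %in% feats))

  fup <- assemble_feature_table(coh, templates = tpl, feature_set = "proposed",
                                followup = TRUE, keypoints = kp)
  expect_false(any(c("sex", "age", "education") %in% names(fup)))

  # a missing block yields NA flags, not failure
  rec <- coh$records[[1]]
  rec$trajectories$B2 <- NULL
  mixed <- c(list(rec), coh$records[-1])
  tab <- assemble_feature_table(mixed, templates = tpl,
                                feature_set = "proposed", keypoints = kp)
  expect_true(is.na(tab$completion_B2[1]))
  expect_false(anyNA(tab$completion_B2[-1]))
})

test_that("anova_screen reproduces the worked two-group example", {
  tab <- structure(
    data.frame(subject_id = sprintf("s%d", 1:6),
               label = factor(rep(c("HC", "AD"), each = 3),
                              levels = c("HC", "MCI", "AD")),
               f = c(1, 2, 3, 2, 3, 4)),
    class = c("tmt_features", "data.frame"))
  res <- anova_screen(tab)
  expect_equal(res$statistic, 1.5)
  expect_equal(res$p, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(res$p, 3), 0.288)
})

test_that("anova_screen handles identical groups and degenerate features", {
  tab <- structure(
    data.frame(subject_id = sprintf("s%d", 1:8),
               label = factor(rep(c("HC", "MCI"), each = 4),
                              levels = c("HC", "MCI", "AD")),
               same = rep(c(1, 2, 3, 4), 2),
               flat = rep(5, 8)),
    class = c("tmt_features", "data.frame"))
  res <- anova_screen(tab, adjust = TRUE)
  expect_gt(res$p[res$feature == "same"], 0.99)
  expect_true(res$degenerate[res$feature == "flat"])
  expect_true("p_bh" %in% names(res))
})

test_that("cross-validation separates separable classes and is deterministic", {
  tab <- make_feature_table(n_per_class = 25, shift = 8, seed = 2)
  r <- cross_validate(tab, task = "HCvsAD", folds = 5, seed = 9)
  expect_equal(unname(r$metrics["accuracy"]), 1.0)
  expect_equal(unname(r$metrics["auc"]), 1.0)
  r2 <- cross_validate(tab, task = "HCvsAD", folds = 5, seed = 9)
  expect_identical(r$metrics, r2$metrics)
  expect_identical(r$per_fold, r2$per_fold)
  # every subject lands in exactly one test fold, stratified
  fa <- r$fold_assignment
  expect_setequal(fa$subject_id, tab$subject_id)
  folds_per_class <- table(fa$label, fa$fold)
  expect_true(all(folds_per_class == 5))
})

test_that("all shipped models run and bound their metrics", {
  tab <- make_feature_table(n_per_class = 20, shift = 3, seed = 5)
  for (m in c("random_forest", "svc", "gbdt")) {
    r <- cross_validate(tab, task = "HCvsAD", model = m, folds = 4, seed = 3)
    expect_true(all(r$metrics >= 0 & r$metrics <= 1))
    expect_gt(unname(r$metrics["accuracy"]), 0.8)
  }
})

test_that("holdout evaluation honours the column contract and relabeling", {
  tab <- make_feature_table(n_per_class = 25, shift = 4, seed = 7)
  fit <- fit_screening_model(tab, task = "HCvsAD", seed = 2)
  # resubstitution sanity bound
  rep0 <- evaluate_holdout(fit, tab)
  expect_gte(unname(rep0$metrics["accuracy"]), 0.95)
  # distributional stability on a fresh draw from the same generator
  tab2 <- make_feature_table(n_per_class = 25, shift = 4, seed = 8)
  rep1 <- evaluate_holdout(fit, tab2)
  expect_gt(unname(rep1$metrics["accuracy"]), 0.8)
  # missing column is an error
  broken <- tab2; broken$signal <- NULL
  expect_error(evaluate_holdout(fit, broken), "signal")

  # ADvsOthers keeps every subject, with n(AD) positives
  tab3 <- make_feature_table(n_per_class = 10, shift = 4, seed = 9)
  tab3$label <- factor(rep(c("HC", "MCI", "AD"), length.out = nrow(tab3)),
                       levels = c("HC", "MCI", "AD"))
  fit3 <- fit_screening_model(tab3, task = "ADvsOthers", seed = 2)
  rep3 <- evaluate_holdout(fit3, tab3)
  expect_equal(rep3$n, nrow(tab3))
  expect_equal(sum(rep3$scores$truth == "pos"), sum(tab3$label == "AD"))
})

test_that("median imputation with indicators handles missing features", {
  tab <- make_feature_table(n_per_class = 15, shift = 5, seed = 11)
  tab$signal[c(3, 20)] <- NA
  fit <- fit_screening_model(tab, task = "HCvsAD", seed = 4)
  expect_true("signal" %in% fit$imputer$indicator_cols)
  r <- evaluate_holdout(fit, tab)
  expect_true(all(is.finite(r$scores$score)))
})

test_that("grouped importance finds planted signal and is additive", {
  tab <- make_feature_table(n_per_class = 40, n_noise = 20, shift = 3, seed = 13)
  tab$flatline <- 1  # constant feature
  fit <- fit_screening_model(tab, task = "HCvsAD", seed = 6)
  imp <- grouped_importance(fit, tab, n_perm = 5, seed = 6)
  expect_equal(imp$per_feature$feature[1], "signal")
  expect_lt(imp$per_feature$importance[imp$per_feature$feature == "flatline"],
            1e-12)
  # group aggregates equal member sums, and totals agree
  sums <- tapply(imp$per_feature$importance, imp$per_feature$group, sum)
  expect_equal(sort(as.numeric(sums)), sort(imp$per_group$importance))
  expect_equal(sum(imp$per_feature$importance), sum(imp$per_group$importance))
})

test_that("importance groups map feature names to their families", {
  grp <- default_feature_grouping(c("completion_A2", "prep_B1", "exec_B2",
                                    "pmean_A1", "pmin_B2", "pmax_A2",
                                    "jerk_B1", "tmpl_dtwd_A2", "tmpl_vq_B2",
                                    "tmpl_vqw_B2", "tdiff_A2B2", "tratio_A2B2",
                                    "age", "errors_B2", "jerk_B1_missing"))
  expect_equal(unname(grp["tmpl_vq_B2"]), "VQ without weights")
  expect_equal(unname(grp["tmpl_vqw_B2"]), "VQ with relative weights")
  expect_equal(unname(grp["tdiff_A2B2"]), "completion time")
  expect_equal(unname(grp["jerk_B1_missing"]), "jerk")
  expect_equal(unname(grp["errors_B2"]), "interaction counts")
})
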