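#' Cross-validated pairwise screening
#'
#' Stratified k-fold cross-validation of a pairwise impairment classifier.
#' When `x` is a cohort (subject records), the full training protocol is
#' honoured fold by fold: the per-block reference templates are re-selected
#' from the *training fold's* healthy controls only, template-based
#' features are recomputed against those references, the imputer is fitted
#' on training rows, and the classifier is trained on the training-fold
#' subjects of the two task classes and evaluated on the test fold. Fold
#' assignment, subset draws, clustering initialisations and model fits all
#' derive from `seed`, so identical seeds give identical reports. Reported
#' metrics are means over folds.
#'
#' When `x` is an already-assembled feature table, the table's columns are
#' used as-is (no per-fold template work); this path serves feature sets
#' without templates and simulation studies on synthetic feature matrices.
#'
#' @param x a `tmt_cohort` / list of [subject_record()]s, or a
#'   `tmt_features` table.
#' @param task `"HCvsMCI"`, `"HCvsAD"`, `"MCIvsAD"` or `"ADvsOthers"`.
#' @param model `"random_forest"`, `"svc"` or `"gbdt"`.
#' @param folds number of folds (default 5).
#' @param seed integer seed for all randomness.
#' @param feature_set,followup passed to [assemble_feature_table()]
#'   (cohort input only).
#' @param k,sigma,subset_size,dtw_method,radius template pipeline
#'   parameters (cohort input only).
#' @param keypoints optional precomputed [cohort_keypoints()].
#' @return A `tmt_report`: mean metrics, per-fold metrics, and the per-fold
#'   template reference ids (cohort input).
#' @export
cross_validate <- function(x, task, model = "random_forest", folds = 5L,
                           seed = 1L,
                           feature_set = c("proposed", "conventional", "all"),
                           followup = FALSE, k = 40L, sigma = 0.1,
                           subset_size = 10L,
                           dtw_method = c("fast", "exact"), radius = 1L,
                           keypoints = NULL) {
  feature_set <- match.arg(feature_set)
  dtw_method <- match.arg(dtw_method)
  folds <- as.integer(folds)
  if (folds < 2) stop("`folds` must be >= 2")
  tc <- task_classes(task)

  if (inherits(x, "tmt_features")) {
    cohort_mode <- FALSE
    base_table <- x
    records <- NULL
  } else {
    cohort_mode <- TRUE
    records <- as_records(x)
    need_templates <- feature_set %in% c("proposed", "all")
    if (need_templates && is.null(keypoints))
      keypoints <- cohort_keypoints(records, k = k, sigma = sigma, seed = seed)
    base_table <- NULL
  }

  labels <- if (cohort_mode)
    vapply(records, function(r) r$group %||% NA_character_, character(1))
  else as.character(base_table$label)
  subj_ids <- if (cohort_mode)
    vapply(records, `[[`, character(1), "subject_id")
  else base_table$subject_id

  in_task <- labels %in% c(tc$positive, tc$negative)
  task_y <- ifelse(labels %in% tc$positive, "pos", "neg")
  per_class_n <- table(task_y[in_task])
  if (length(per_class_n) < 2) stop("both task classes must be present")
  if (any(per_class_n < folds))
    stop("each task class needs at least `folds` subjects")

  fold_of <- assign_folds(labels, folds, derive_seed(seed, "folds"))

  fold_rows <- list()
  fold_templates <- list()
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    if (cohort_mode) {
      templates <- NULL
      if (feature_set %in% c("proposed", "all")) {
        templates <- fit_templates(records[train_idx],
                                   subset_size = subset_size,
                                   seed = derive_seed(seed, "tpl_fold", f),
                                   method = dtw_method, radius = radius,
                                   k = k, sigma = sigma, keypoints = keypoints)
        fold_templates[[f]] <- vapply(templates, attr, character(1),
                                      "subject_id")
      }
      tab <- assemble_feature_table(records, templates = templates,
                                    feature_set = feature_set,
                                    followup = followup,
                                    keypoints = keypoints,
                                    k = k, sigma = sigma, seed = seed)
    } else {
      tab <- base_table
    }
    tr <- tab[intersect(train_idx, which(in_task)), , drop = FALSE]
    te <- tab[intersect(test_idx, which(in_task)), , drop = FALSE]
    y_tr <- task_y[intersect(train_idx, which(in_task))]
    y_te <- task_y[intersect(test_idx, which(in_task))]
    feats <- feature_columns(tab)
    imp <- fit_imputer(tr[, feats, drop = FALSE])
    x_tr <- apply_imputer(imp, tr[, feats, drop = FALSE])
    x_te <- apply_imputer(imp, te[, feats, drop = FALSE])
    clf <- fit_classifier(x_tr, y_tr, model = model,
                          seed = derive_seed(seed, "fit", f))
    score <- predict_score(clf, x_te)
    m <- binary_metrics(y_te, score, score_threshold(clf))
    fold_rows[[f]] <- data.frame(fold = f, n_test = length(y_te), t(m))
  }
  per_fold <- do.call(rbind, fold_rows)
  metrics <- colMeans(per_fold[, c("accuracy", "auc", "sensitivity",
                                   "specificity")], na.rm = TRUE)
  structure(list(task = task, model = model, folds = folds, seed = seed,
                 metrics = metrics, per_fold = per_fold,
                 fold_templates = if (length(fold_templates)) fold_templates,
                 fold_assignment = data.frame(subject_id = subj_ids,
                                              label = labels,
                                              fold = fold_of)),
            class = "tmt_report")
}

# Stratified fold assignment: within each label (including NA as its own
# stratum) subjects are shuffled and dealt round-robin into folds.
assign_folds <- function(labels, folds, seed) {
  n <- length(labels)
  fold_of <- integer(n)
  strata <- split(seq_len(n), addNA(factor(labels)), drop = TRUE)
  local_seed(seed, {
    for (s in strata) {
      sh <- if (length(s) > 1) sample(s) else s
      fold_of[sh] <- rep_len(seq_len(folds), length(sh))
    }
  })
  fold_of
}
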