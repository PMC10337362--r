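#' Pairwise screening tasks
#'
#' Each task is a binary contrast between diagnostic groups. The positive
#' class is always the more impaired one (MCI over HC, AD over HC or MCI,
#' AD against everyone in `ADvsOthers`), which fixes the meaning of
#' sensitivity (detecting impairment) and specificity.
#'
#' @param task task name.
#' @return List with `positive`, `negative` (group vectors) and the binary
#'   class labels used internally.
#' @keywords internal
task_classes <- function(task = c("HCvsMCI", "HCvsAD", "MCIvsAD", "ADvsOthers")) {
  task <- match.arg(task)
  switch(task,
    HCvsMCI = list(positive = "MCI", negative = "HC"),
    HCvsAD = list(positive = "AD", negative = "HC"),
    MCIvsAD = list(positive = "AD", negative = "MCI"),
    ADvsOthers = list(positive = "AD", negative = c("HC", "MCI")))
}

# ---- imputation ------------------------------------------------------------

# Training-fold median imputation with missingness indicator columns for
# every feature that is incomplete in the training data.
fit_imputer <- function(x) {
  meds <- vapply(x, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1))
  list(medians = meds, indicator_cols = names(x)[vapply(x, anyNA, logical(1))])
}

apply_imputer <- function(imp, x) {
  for (nm in imp$indicator_cols)
    x[[paste0(nm, "_missing")]] <- as.numeric(is.na(x[[nm]]))
  for (nm in names(imp$medians))
    x[[nm]][is.na(x[[nm]])] <- imp$medians[[nm]]
  x
}

# ---- model zoo -------------------------------------------------------------

# Fits one binary classifier at library-default hyperparameters and wraps a
# uniform scoring interface: higher score = more likely positive class.
fit_classifier <- function(x, y, model = c("random_forest", "svc", "gbdt"),
                           seed = 1L) {
  model <- match.arg(model)
  y <- factor(y, levels = c("neg", "pos"))
  x <- as.matrix(x)
  fit <- local_seed(seed, switch(model,
    random_forest = randomForest::randomForest(x = x, y = y),
    svc = suppressWarnings(e1071::svm(x = x, y = y, kernel = "radial")),
    gbdt = xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    seed = as.integer(seed)),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(y == "pos"),
                                  nthread = 1),
      nrounds = 100, verbose = 0)))
  structure(list(model = model, fit = fit, features = colnames(x), seed = seed),
            class = "tmt_classifier")
}

predict_score <- function(clf, x) {
  x <- as.matrix(x[, clf$features, drop = FALSE])
  switch(clf$model,
    random_forest = unname(predict(clf$fit, x, type = "prob")[, "pos"]),
    svc = {
      pr <- predict(clf$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      s <- dv[, 1]
      # decision values are signed towards the first named class
      if (grepl("^pos", colnames(dv)[1])) unname(s) else -unname(s)
    },
    gbdt = unname(predict(clf$fit, xgboost::xgb.DMatrix(x, nthread = 1))))
}

score_threshold <- function(clf) if (clf$model == "svc") 0 else 0.5

# ---- metrics ---------------------------------------------------------------

binary_metrics <- function(truth, score, threshold) {
  pred <- ifelse(score > threshold, "pos", "neg")
  acc <- mean(pred == truth)
  tp <- sum(pred == "pos" & truth == "pos")
  fn <- sum(pred == "neg" & truth == "pos")
  tn <- sum(pred == "neg" & truth == "neg")
  fp <- sum(pred == "pos" & truth == "neg")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- if (length(unique(truth)) == 2) {
    r <- pROC::roc(response = truth, predictor = score,
                   levels = c("neg", "pos"), direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(r))
  } else NA_real_
  c(accuracy = acc, auc = auc, sensitivity = sens, specificity = spec)
}

# ---- training / holdout ----------------------------------------------------

#' Fit a screening classifier on a feature table
#'
#' Trains one binary classifier (default hyperparameters, seeded) for a
#' pairwise task on an assembled feature table. Missing values are imputed
#' by training medians, with missingness-indicator columns added for
#' features incomplete at training time.
#'
#' @param table `tmt_features` with labels.
#' @param task see [task_classes()]: `"HCvsMCI"`, `"HCvsAD"`, `"MCIvsAD"`
#'   or `"ADvsOthers"`.
#' @param model `"random_forest"` (reference model), `"svc"` or `"gbdt"`.
#' @param seed integer seed.
#' @return A `tmt_screening_fit` carrying the classifier, imputer and
#'   column contract for holdout evaluation.
#' @export
fit_screening_model <- function(table, task, model = "random_forest", seed = 1L) {
  tc <- task_classes(task)
  sel <- table$label %in% c(tc$positive, tc$negative)
  tab <- table[sel & !is.na(table$label), , drop = FALSE]
  y <- ifelse(as.character(tab$label) %in% tc$positive, "pos", "neg")
  if (length(unique(y)) < 2) stop("both task classes must be present")
  feats <- feature_columns(tab)
  x <- tab[, feats, drop = FALSE]
  imp <- fit_imputer(x)
  x <- apply_imputer(imp, x)
  clf <- fit_classifier(x, y, model = model, seed = seed)
  structure(list(task = task, classes = tc, model = model, seed = seed,
                 imputer = imp, feature_names = feats, classifier = clf),
            class = "tmt_screening_fit")
}

#' Evaluate a fitted screening model on a held-out cohort
#'
#' Scores an untouched feature table (e.g. follow-up assessments of the
#' same clinic, assembled with `followup = TRUE` so identity-related
#' columns are absent at train and test time alike) with a
#' [fit_screening_model()] fit. For `ADvsOthers` the HC and MCI rows are
#' relabelled as the negative class.
#'
#' @param fit a `tmt_screening_fit`.
#' @param holdout a `tmt_features` table with the same feature columns.
#' @return A `tmt_report` with overall metrics and per-subject scores.
#' @export
evaluate_holdout <- function(fit, holdout) {
  stopifnot(inherits(fit, "tmt_screening_fit"))
  missing_cols <- setdiff(fit$feature_names, names(holdout))
  if (length(missing_cols))
    stop("holdout table lacks training columns: ",
         paste(missing_cols, collapse = ", "))
  tc <- fit$classes
  sel <- holdout$label %in% c(tc$positive, tc$negative) & !is.na(holdout$label)
  tab <- holdout[sel, , drop = FALSE]
  y <- ifelse(as.character(tab$label) %in% tc$positive, "pos", "neg")
  x <- apply_imputer(fit$imputer, tab[, fit$feature_names, drop = FALSE])
  score <- predict_score(fit$classifier, x)
  m <- binary_metrics(y, score, score_threshold(fit$classifier))
  structure(list(task = fit$task, model = fit$model, seed = fit$seed,
                 metrics = m, n = nrow(tab),
                 scores = data.frame(subject_id = tab$subject_id,
                                     truth = y, score = score)),
            class = "tmt_report")
}

#' @export
print.tmt_report <- function(x, ...) {
  cat(sprintf("<tmt_report> %s / %s%s\n", x$task, x$model,
              if (!is.null(x$folds)) sprintf(" (%d-fold CV)", x$folds) else ""))
  print(round(x$metrics, 3))
  invisible(x)
}
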