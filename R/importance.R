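#' Grouped permutation feature importance
#'
#' Per-feature attribution via a permutation backend: each feature column
#' is permuted `n_perm` times and the importance is the mean absolute
#' change in the classifier's predicted positive-class score, averaged
#' over subjects and permutations. Attributions of features in the same
#' family are then summed into group aggregates (the group value is by
#' construction the sum of its members, mirroring additive attribution
#' schemes such as SHAP; the attribution backend is pluggable through
#' `backend`).
#'
#' The default grouping collects block features into the families used in
#' screening reports: completion / preparation / execution time, averaged
#' / minimal / maximal write pressure, jerk, DTWD, VQ without weights, VQ
#' with relative weights, plus demographics and interaction counts.
#'
#' @param fit a [fit_screening_model()] result.
#' @param table feature table to attribute on (typically the training
#'   table).
#' @param grouping named character vector mapping feature name to group
#'   name; defaults to [default_feature_grouping()] of the fit's features.
#' @param n_perm permutations per feature.
#' @param seed integer seed.
#' @param backend attribution backend; `"permutation"` is the only shipped
#'   one.
#' @return A `tmt_importance`: list with `per_feature` (data frame
#'   `feature`, `group`, `importance`) and `per_group` (data frame `group`,
#'   `importance`), each sorted decreasing.
#' @export
grouped_importance <- function(fit, table, grouping = NULL, n_perm = 10L,
                               seed = 1L, backend = "permutation") {
  stopifnot(inherits(fit, "tmt_screening_fit"))
  backend <- match.arg(backend)
  tc <- fit$classes
  sel <- table$label %in% c(tc$positive, tc$negative) & !is.na(table$label)
  tab <- table[sel, , drop = FALSE]
  x <- apply_imputer(fit$imputer, tab[, fit$feature_names, drop = FALSE])
  base_score <- predict_score(fit$classifier, x)
  feats <- fit$feature_names
  if (is.null(grouping)) grouping <- default_feature_grouping(feats)
  imp <- local_seed(seed, vapply(feats, function(f) {
    deltas <- vapply(seq_len(n_perm), function(r) {
      xp <- x
      xp[[f]] <- x[[f]][sample.int(nrow(x))]
      mean(abs(predict_score(fit$classifier, xp) - base_score))
    }, numeric(1))
    mean(deltas)
  }, numeric(1)))
  per_feature <- data.frame(feature = feats,
                            group = unname(grouping[feats]),
                            importance = unname(imp))
  agg <- aggregate(importance ~ group, per_feature, sum)
  per_feature <- per_feature[order(-per_feature$importance), ]
  agg <- agg[order(-agg$importance), ]
  rownames(per_feature) <- rownames(agg) <- NULL
  structure(list(per_feature = per_feature, per_group = agg,
                 backend = backend, n_perm = n_perm, seed = seed),
            class = "tmt_importance")
}

#' Default feature-family grouping
#'
#' @param features character vector of feature names as produced by
#'   [assemble_feature_table()].
#' @return Named character vector feature -> group.
#' @export
default_feature_grouping <- function(features) {
  grp <- vapply(features, function(f) {
    stem <- sub("_(A1|A2|B1|B2)(_missing)?$", "", f)
    stem <- sub("_missing$", "", stem)
    switch(stem,
      completion = , tdiff_A2B2 = , tratio_A2B2 = "completion time",
      prep = "preparation time",
      exec = "execution time",
      pmean = "averaged write pressure",
      pmin = "minimal write pressure",
      pmax = "maximal write pressure",
      jerk = "jerk",
      tmpl_dtwd = "DTWD",
      tmpl_vq = "VQ without weights",
      tmpl_vqw = "VQ with relative weights",
      sex = , age = , education = "demographics",
      errors = , penup_warnings = , prompts = "interaction counts",
      stem)
  }, character(1))
  names(grp) <- features
  grp
}

#' @export
print.tmt_importance <- function(x, ...) {
  cat("<tmt_importance> (", x$backend, " backend)\n", sep = "")
  print(x$per_group, digits = 3)
  invisible(x)
}
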