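#' Per-feature one-way ANOVA screen
#'
#' For every numeric feature and every pair of diagnostic groups present,
#' computes the one-way ANOVA F test (equal-variance, two groups, so this
#' is the squared two-sample t test) of a group difference in that
#' feature. Missing values are dropped listwise per feature. No
#' multiple-testing correction is applied by default — the p-values are
#' reported raw, as in conventional feature-screening tables — but
#' `adjust = TRUE` appends a Benjamini-Hochberg column (computed across
#' all feature x pair tests) as a clearly separate extension.
#'
#' @param table a `tmt_features` data frame with a `label` column.
#' @param adjust add a `p_bh` Benjamini-Hochberg column.
#' @return Data frame: `feature`, `pair`, `n1`, `n2`, `statistic` (F),
#'   `p`, optionally `p_bh`. Features with zero variance in both groups of
#'   a pair get `NA` with `degenerate = TRUE`.
#' @export
anova_screen <- function(table, adjust = FALSE) {
  stopifnot(!is.null(table$label))
  lvls <- levels(droplevels(table$label[!is.na(table$label)]))
  if (length(lvls) < 2) stop("need at least 2 groups with subjects")
  pairs <- utils::combn(lvls, 2, simplify = FALSE)
  feats <- feature_columns(table)
  out <- list()
  for (f in feats) {
    for (pr in pairs) {
      sel <- table$label %in% pr & !is.na(table[[f]])
      x <- table[[f]][sel]
      g <- droplevels(table$label[sel])
      n <- table(g)
      if (length(n) < 2 || any(n < 2)) next
      if (sd(x) == 0 || all(tapply(x, g, sd) == 0)) {
        out[[length(out) + 1L]] <- data.frame(
          feature = f, pair = paste(pr, collapse = "vs"),
          n1 = n[[1]], n2 = n[[2]], statistic = NA_real_, p = NA_real_,
          degenerate = TRUE)
        next
      }
      fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        feature = f, pair = paste(pr, collapse = "vs"),
        n1 = n[[1]], n2 = n[[2]],
        statistic = unname(fit$statistic), p = unname(fit$p.value),
        degenerate = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (adjust) res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res
}
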