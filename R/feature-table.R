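#' Precompute key-point sequences for a cohort
#'
#' Key-point extraction depends only on the trajectory, the codebook size,
#' the smoothing parameter, and a per-trajectory seed derived
#' deterministically from `seed` and the subject/block identity — never on
#' the cross-validation fold. Computing them once and reusing them across
#' folds is therefore leakage-free and saves most of the clustering cost.
#'
#' @param records list of [subject_record()]s (or a `tmt_cohort`).
#' @param k,sigma key-point extraction parameters.
#' @param seed integer base seed.
#' @return Nested list: `keypoints[[subject_id]][[block_key]]`.
#' @export
cohort_keypoints <- function(records, k = 40L, sigma = 0.1, seed = 1L) {
  records <- as_records(records)
  out <- list()
  for (rec in records) {
    kps <- list()
    for (key in names(rec$trajectories)) {
      kps[[key]] <- extract_keypoints(
        rec$trajectories[[key]], k = k, sigma = sigma,
        seed = derive_seed(seed, "kp", rec$subject_id, key))
    }
    out[[rec$subject_id]] <- kps
  }
  out
}

as_records <- function(x) {
  if (inherits(x, "tmt_cohort")) x$records
  else if (is.list(x) && all(vapply(x, inherits, logical(1), "tmt_subject"))) x
  else stop("expected a tmt_cohort or a list of subject records")
}

BLOCK_KEYS <- c("A1", "A2", "B1", "B2")

#' Assemble the subject-by-feature table
#'
#' Three feature sets are defined. `"conventional"` mirrors classical
#' paper-form scoring: the four block completion times, demographics (sex,
#' age, education) and the six examiner interaction counts.  `"proposed"`
#' holds everything the digitised trace adds — all kinematic block features,
#' the A2/B2 cross-block difference and ratio, the template-based features —
#' plus demographics, but deliberately excludes the interaction counts
#' (they require an examiner in the loop). `"all"` is their union.
#' `followup = TRUE` additionally drops sex, age and education, the
#' identity-related columns excluded when scoring a re-tested cohort
#' against a model trained at baseline.
#'
#' Missing blocks or undefined features yield `NA` entries, which the
#' classifier front end imputes; a subject with no trajectories still
#' produces a row.
#'
#' @param records list of [subject_record()]s or a `tmt_cohort`.
#' @param templates named list (`A1`..`B2`) of reference key-point
#'   sequences; required unless `feature_set = "conventional"`.
#' @param feature_set `"proposed"`, `"conventional"` or `"all"`.
#' @param followup drop identity-related columns (see above).
#' @param keypoints optional precomputed [cohort_keypoints()] result.
#' @param k,sigma,seed key-point parameters used when `keypoints` is `NULL`.
#' @return A `tmt_features` data frame: `subject_id`, `label` (factor,
#'   `NA` allowed), then one numeric column per feature.
#' @export
assemble_feature_table <- function(records, templates = NULL,
                                   feature_set = c("proposed", "conventional", "all"),
                                   followup = FALSE, keypoints = NULL,
                                   k = 40L, sigma = 0.1, seed = 1L) {
  feature_set <- match.arg(feature_set)
  records <- as_records(records)
  need_templates <- feature_set %in% c("proposed", "all")
  if (need_templates && is.null(templates))
    stop("`templates` needed for feature set '", feature_set, "'")
  if (need_templates && is.null(keypoints))
    keypoints <- cohort_keypoints(records, k = k, sigma = sigma, seed = seed)

  kin_names <- c("completion", "prep", "exec", "pmean", "pmin", "pmax", "jerk")
  rows <- lapply(records, function(rec) {
    row <- list(subject_id = rec$subject_id,
                label = rec$group %||% NA_character_)
    for (key in BLOCK_KEYS) {
      tr <- rec$trajectories[[key]]
      bf <- if (is.null(tr)) setNames(rep(NA_real_, 7), kin_names)
            else block_features_cached(tr, rec$subject_id, key)
      for (nm in kin_names) row[[paste0(nm, "_", key)]] <- unname(bf[[nm]])
    }
    tA2 <- row$completion_A2; tB2 <- row$completion_B2
    row$tdiff_A2B2 <- if (is.na(tA2) || is.na(tB2)) NA_real_
                      else time_difference(tA2, tB2)
    row$tratio_A2B2 <- if (is.na(tA2) || is.na(tB2)) NA_real_
                       else as.numeric(time_ratio(tA2, tB2))
    if (need_templates) {
      for (key in BLOCK_KEYS) {
        kp <- keypoints[[rec$subject_id]][[key]]
        tf <- if (is.null(kp) || is.null(templates[[key]]))
          c(dtwd = NA_real_, vq_unweighted = NA_real_, vq_weighted = NA_real_)
        else template_features(templates[[key]], kp)
        row[[paste0("tmpl_dtwd_", key)]] <- unname(tf[["dtwd"]])
        row[[paste0("tmpl_vq_", key)]] <- unname(tf[["vq_unweighted"]])
        row[[paste0("tmpl_vqw_", key)]] <- unname(tf[["vq_weighted"]])
      }
    }
    row$sex <- if (is.null(rec$sex)) NA_real_ else as.numeric(rec$sex == "F")
    row$age <- rec$age %||% NA_real_
    row$education <- rec$education %||% NA_real_
    ic_names <- c("errors_A2", "errors_B2", "penup_warnings_A2",
                  "penup_warnings_B2", "prompts_A2", "prompts_B2")
    for (nm in ic_names)
      row[[nm]] <- if (is.null(rec$interaction_counts)) NA_real_
                   else unname(rec$interaction_counts[nm])
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  keep <- switch(feature_set,
    conventional = c(paste0("completion_", BLOCK_KEYS),
                     "sex", "age", "education",
                     "errors_A2", "errors_B2", "penup_warnings_A2",
                     "penup_warnings_B2", "prompts_A2", "prompts_B2"),
    proposed = c(outer_names(kin_names), "tdiff_A2B2", "tratio_A2B2",
                 outer_names(c("tmpl_dtwd", "tmpl_vq", "tmpl_vqw")),
                 "sex", "age", "education"),
    all = setdiff(names(tab), c("subject_id", "label")))
  if (followup) keep <- setdiff(keep, c("sex", "age", "education"))
  tab <- tab[, c("subject_id", "label", keep), drop = FALSE]
  tab$label <- factor(tab$label, levels = c("HC", "MCI", "AD"))
  rownames(tab) <- NULL
  structure(tab, class = c("tmt_features", "data.frame"),
            feature_set = feature_set, followup = followup)
}

outer_names <- function(stems) {
  as.vector(t(outer(stems, BLOCK_KEYS, paste, sep = "_")))
}

feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "label"))
}

#' Select per-block templates from healthy-control records
#'
#' Runs [select_template()] over the HC trajectories of each (part, block)
#' and extracts the reference key-point sequences. This is the
#' template-fitting step of training; in cross-validation it is re-run per
#' fold on the fold's training subjects only.
#'
#' @param records HC-containing record list or `tmt_cohort`.
#' @param subset_size,seed,method,radius passed to [select_template()].
#' @param k,sigma,keypoints key-point parameters / precomputed keypoints.
#' @return Named list (`A1`..`B2`) of reference `tmt_keypoints`.
#' @export
fit_templates <- function(records, subset_size = 10L, seed = 1L,
                          method = c("exact", "fast"), radius = 1L,
                          k = 40L, sigma = 0.1, keypoints = NULL) {
  method <- match.arg(method)
  records <- as_records(records)
  hc <- Filter(function(r) identical(r$group, "HC"), records)
  if (!length(hc)) stop("no healthy-control records to select a template from")
  templates <- list()
  for (key in BLOCK_KEYS) {
    pool <- list()
    for (rec in hc)
      if (!is.null(rec$trajectories[[key]]))
        pool[[rec$subject_id]] <- rec$trajectories[[key]]
    if (!length(pool)) next
    # selection is deterministic in (pool data, parameters); memoise it so
    # repeated runs over the same training pool (e.g. the same fold across
    # several pairwise tasks) skip the DTW matrix
    fp <- vapply(pool, function(tr)
      nrow(tr) + sum(tr$x) / 1e6 + sum(tr$t), numeric(1))
    ckey <- paste(key, subset_size, seed, method, radius, k, sigma,
                  paste(names(pool), collapse = ","),
                  paste(format(fp, digits = 15), collapse = ","), sep = "|")
    if (!is.null(.template_cache[[ckey]])) {
      templates[[key]] <- .template_cache[[ckey]]
      next
    }
    ref_traj <- select_template(pool, subset_size = subset_size,
                                seed = derive_seed(seed, "tpl", key),
                                method = method, radius = radius)
    sid <- attr(ref_traj, "subject_id")
    templates[[key]] <- if (!is.null(keypoints) &&
                            !is.null(keypoints[[sid]][[key]]))
      keypoints[[sid]][[key]]
    else extract_keypoints(ref_traj, k = k, sigma = sigma,
                           seed = derive_seed(seed, "kp", sid, key))
    .template_cache[[ckey]] <- templates[[key]]
  }
  templates
}

.template_cache <- new.env(parent = emptyenv())

# kinematic block features depend only on the trajectory, so repeated
# assemblies (one per CV fold) reuse them; keyed by a data fingerprint
block_features_cached <- function(tr, sid, key) {
  ck <- paste(sid, key, nrow(tr), format(sum(tr$t), digits = 15),
              format(sum(tr$pressure), digits = 15), sep = "|")
  hit <- .template_cache[[ck]]
  if (!is.null(hit)) return(hit)
  .template_cache[[ck]] <- block_features(tr)
}

#' Read or write a feature table as delimited text
#'
#' @param table a `tmt_features` data frame.
#' @param path CSV file.
#' @return `write_feature_table()`: `invisible(path)`;
#'   `read_feature_table()`: the table.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$label <- factor(tab$label, levels = c("HC", "MCI", "AD"))
  structure(tab, class = c("tmt_features", "data.frame"))
}
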