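#' Select a reference trajectory from the healthy-control pool
#'
#' Every healthy-control trace is assumed to share structure with the ideal
#' connecting path, so the trace most similar to its peers serves as the
#' template all trajectories are compared against. A subset of
#' `subset_size` trajectories (default 10) is sampled without replacement
#' from the pool using `seed`; within the subset the trajectory whose
#' summed DTW distance to the other subset members is smallest is returned.
#' Ties are broken by the lexicographically lowest subject id.
#'
#' @param hc_trajs list of [trajectory()] objects (healthy controls, one
#'   (part, block)).
#' @param subset_size number of trajectories to sample (capped at the pool
#'   size).
#' @param seed integer seed for the subset draw.
#' @param method,radius DTW variant for the intra-subset distances; the
#'   exact dynamic program is the default so selection is reproducible
#'   against a brute-force distance matrix.
#' @return The selected trajectory, with attribute `dtwd_rowsum`.
#' @export
select_template <- function(hc_trajs, subset_size = 10L, seed = 1L,
                            method = c("exact", "fast"), radius = 1L) {
  method <- match.arg(method)
  n <- length(hc_trajs)
  if (n < 1) stop("empty healthy-control pool")
  if (n == 1) return(hc_trajs[[1]])
  m <- min(as.integer(subset_size), n)
  pick <- local_seed(seed, sample.int(n, m))
  subset <- hc_trajs[pick]
  if (m == 1) return(subset[[1]])
  D <- pairwise_dtwd(subset, method = method, radius = radius)
  rowsums <- rowSums(D)
  best <- which(rowsums == min(rowsums))
  if (length(best) > 1) {
    sids <- vapply(subset[best], attr, character(1), "subject_id")
    best <- best[order(sids)][1]
  }
  out <- subset[[best]]
  attr(out, "dtwd_rowsum") <- unname(rowsums[best])
  out
}

#' Template-based distance features
#'
#' Compares a trajectory's key-point sequence against the reference's:
#' * `dtwd` — exact DTW distance between the two ordered key-point center
#'   sequences;
#' * `vq_unweighted` — mean Euclidean distance over temporally index-paired
#'   key points (up to the shorter length);
#' * `vq_weighted` — the same pairing averaged with the trajectory's
#'   relative key-point weights, renormalised by their sum so the feature
#'   remains a length-scale quantity.
#'
#' @param ref reference key points ([extract_keypoints()] of the template).
#' @param traj_kp key points of the trajectory under evaluation.
#' @return Named numeric `c(dtwd=, vq_unweighted=, vq_weighted=)`, all
#'   nonnegative, all zero when `traj_kp` equals `ref`.
#' @export
template_features <- function(ref, traj_kp) {
  if (!nrow(ref) || !nrow(traj_kp)) stop("empty key-point sequence")
  rc <- cbind(ref$cx, ref$cy)
  tc <- cbind(traj_kp$cx, traj_kp$cy)
  m <- min(nrow(rc), nrow(tc))
  d <- sqrt(rowSums((rc[seq_len(m), , drop = FALSE] -
                       tc[seq_len(m), , drop = FALSE])^2))
  w <- traj_kp$weight[seq_len(m)]
  c(dtwd = dtw_distance(rc, tc),
    vq_unweighted = mean(d),
    vq_weighted = sum(w * d) / sum(w))
}

#' Save and reload template archives
#'
#' A trained screening model carries one reference key-point sequence per
#' (part, block). The archive is a JSON document storing, for each block,
#' the reference subject id, the extraction parameters (`k`, `sigma`,
#' `seed`) and the key-point table, so follow-up cohorts can be scored
#' against the original templates.
#'
#' @param templates named list (`"A1"`, `"A2"`, `"B1"`, `"B2"`) of
#'   `tmt_keypoints` objects.
#' @param path archive file.
#' @return `write_templates()`: `invisible(path)`; `read_templates()`: the
#'   named list of `tmt_keypoints`.
#' @export
write_templates <- function(templates, path) {
  doc <- lapply(templates, function(kp) list(
    subject_id = attr(kp, "subject_id"), part = attr(kp, "part"),
    block = attr(kp, "block"), k = attr(kp, "k"),
    sigma = attr(kp, "sigma"), seed = attr(kp, "seed"),
    keypoints = as.data.frame(kp)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(doc, function(entry) {
    kp <- as.data.frame(entry$keypoints)
    class(kp) <- c("tmt_keypoints", "data.frame")
    attr(kp, "subject_id") <- entry$subject_id
    attr(kp, "part") <- entry$part
    attr(kp, "block") <- as.integer(entry$block)
    attr(kp, "k") <- as.integer(entry$k)
    attr(kp, "sigma") <- entry$sigma
    attr(kp, "seed") <- as.integer(entry$seed)
    kp
  })
}
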