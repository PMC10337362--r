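#' Read tablet trajectory files
#'
#' Two on-disk dialects are supported. `"delimited-samples"` is a flat CSV
#' with header `subject_id,part,block,x,y,pressure,t`, one tablet sample per
#' row ('.' decimal separator, UTF-8); subject metadata is not carried.
#' `"structured-records"` is a JSON document with one record per subject
#' holding metadata (group, sex, age, education, interaction counts) plus
#' per-block sample arrays.
#'
#' Raw device timestamps are divided by `time_unit` so that all downstream
#' features are in seconds; the tablet's sampling clock is not standardised,
#' so the caller must declare it (default: timestamps already in seconds).
#'
#' @param path file to read.
#' @param dialect `"delimited-samples"` or `"structured-records"`.
#' @param mode validation mode passed to [trajectory()]; in `"strict"` mode
#'   a decreasing timestamp is an error naming the offending row.
#' @param time_unit number of raw time units per second (e.g. `1000` for
#'   millisecond clocks).
#' @return A list of [subject_record()] objects.
#' @seealso [write_trajectories()]
#' @export
read_trajectories <- function(path, dialect = c("delimited-samples", "structured-records"),
                              mode = c("strict", "lenient"), time_unit = 1) {
  dialect <- match.arg(dialect)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "delimited-samples")
    read_delimited_samples(path, mode, time_unit)
  else
    read_structured_records(path, mode, time_unit)
}

read_delimited_samples <- function(path, mode, time_unit) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "part", "block", "x", "y", "pressure", "t")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("parse error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) return(list())
  df$t <- df$t / time_unit
  # stable within-file order defines sample order; line numbers for messages
  df$.line <- seq_len(nrow(df)) + 1L
  split_key <- paste(df$subject_id, df$part, df$block, sep = "\r")
  groups <- split(df, factor(split_key, levels = unique(split_key)))
  recs <- list()
  for (g in groups) {
    sid <- as.character(g$subject_id[1])
    if (mode == "strict" && any(diff(g$t) < 0)) {
      row <- g$.line[which(diff(g$t) < 0)[1] + 1L]
      stop("validation error: timestamp decreases at line ", row,
           " (subject ", sid, ", ", g$part[1], g$block[1], ")")
    }
    tr <- trajectory(g$x, g$y, g$pressure, g$t, subject_id = sid,
                     part = g$part[1], block = g$block[1], mode = mode)
    key <- paste0(g$part[1], g$block[1])
    if (is.null(recs[[sid]])) recs[[sid]] <- list()
    if (!is.null(recs[[sid]][[key]]))
      stop("duplicate block ", key, " for subject ", sid)
    recs[[sid]][[key]] <- tr
  }
  unname(lapply(names(recs), function(sid)
    subject_record(sid, trajectories = recs[[sid]])))
}

read_structured_records <- function(path, mode, time_unit) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(doc$subjects)) doc <- doc$subjects
  lapply(doc, function(rec) {
    trajs <- list()
    for (key in names(rec$trajectories)) {
      b <- rec$trajectories[[key]]
      trajs[[key]] <- trajectory(
        unlist(b$x), unlist(b$y), unlist(b$pressure), unlist(b$t) / time_unit,
        subject_id = rec$subject_id,
        part = substr(key, 1, 1), block = as.integer(substr(key, 2, 2)),
        mode = mode)
    }
    ic <- rec$interaction_counts
    subject_record(rec$subject_id, trajectories = trajs,
                   group = rec$group %||% NULL,
                   sex = rec$sex %||% NULL,
                   age = rec$age %||% NULL,
                   education = rec$education %||% NULL,
                   interaction_counts = if (length(ic)) unlist(ic) else NULL)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write subject records to disk
#'
#' Inverse of [read_trajectories()]: the written file re-reads to records
#' with bit-identical numeric fields. The delimited dialect keeps full
#' double precision (17 significant digits); the structured dialect is JSON
#' and additionally round-trips subject metadata.
#'
#' @param records list of [subject_record()] objects.
#' @param path output file.
#' @param dialect see [read_trajectories()].
#' @return `invisible(path)`.
#' @export
write_trajectories <- function(records, path,
                               dialect = c("delimited-samples", "structured-records")) {
  dialect <- match.arg(dialect)
  if (dialect == "delimited-samples") {
    rows <- lapply(records, function(rec) {
      do.call(rbind, lapply(names(rec$trajectories), function(key) {
        tr <- rec$trajectories[[key]]
        data.frame(subject_id = rec$subject_id,
                   part = attr(tr, "part"), block = attr(tr, "block"),
                   x = tr$x, y = tr$y, pressure = tr$pressure, t = tr$t)
      }))
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
      df <- data.frame(subject_id = character(), part = character(),
                       block = integer(), x = numeric(), y = numeric(),
                       pressure = numeric(), t = numeric())
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    # format() at 17 digits keeps doubles bit-identical through the round trip
    fmt <- df
    for (col in c("x", "y", "pressure", "t"))
      fmt[[col]] <- formatC(df[[col]], digits = 17, format = "g")
    utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE)
  } else {
    doc <- lapply(records, function(rec) {
      trajs <- lapply(rec$trajectories, function(tr)
        list(x = tr$x, y = tr$y, pressure = tr$pressure, t = tr$t))
      out <- list(subject_id = rec$subject_id, trajectories = trajs)
      for (f in c("group", "sex", "age", "education"))
        if (!is.null(rec[[f]])) out[[f]] <- rec[[f]]
      if (!is.null(rec$interaction_counts))
        out$interaction_counts <- as.list(rec$interaction_counts)
      out
    })
    jsonlite::write_json(list(subjects = doc), path,
                         auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}
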