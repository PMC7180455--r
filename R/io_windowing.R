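#' Write a recording to CSV
#'
#' One row per sample, columns `ax,ay,az` (m/s^2), header row.
#'
#' @param recording A `har_recording`.
#' @param path Output file path.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "har_recording"))
  df <- as.data.frame(recording$samples)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a triaxial recording from CSV
#'
#' Expects numeric rows of width 3 (columns acceleration x, y, z in
#' m/s^2, with or without a header row).  Malformed rows abort with an
#' error naming the offending line.
#'
#' @param path File path.
#' @param subject,activity Labels attached to the recording.
#' @param rate_hz Sampling rate of the file in Hz.
#'
#' @return A `har_recording`.
#' @export
read_recording <- function(path, subject = NA_character_,
                           activity = NA_character_, rate_hz = 51.2) {
  if (!file.exists(path)) stop("file not found: ", path)
  widths <- utils::count.fields(path, sep = ",")
  if (length(widths) == 0L) stop("empty recording file: ", path)
  bad <- which(widths != 3L)
  if (length(bad))
    stop("malformed row (expected 3 comma-separated values) at line ",
         bad[1L], " of ", path)
  first <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.csv(path, header = header,
                        colClasses = rep("character", 3))
  df[] <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  if (length(df) && nrow(df)) {
    na_row <- which(!stats::complete.cases(df))
    if (length(na_row))
      stop("non-numeric value at line ", na_row[1L] + as.integer(header),
           " of ", path)
  }
  if (nrow(df) == 0L) stop("empty recording file: ", path)
  m <- as.matrix(df)
  colnames(m) <- c("ax", "ay", "az")
  structure(list(subject = subject, activity = activity, rate_hz = rate_hz,
                 samples = m, contaminated_segments = integer(0),
                 segment_s = NA_real_),
            class = "har_recording")
}

#' Read every recording listed in a dataset manifest
#'
#' @param dir Directory containing `manifest.csv` and the recording
#'   CSV files written by [generate_dataset] (or any files following
#'   the same layout).
#' @return A list of `har_recording` objects.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i)
    read_recording(file.path(dir, manifest$file[i]),
                   subject = manifest$subject[i],
                   activity = manifest$activity[i],
                   rate_hz = manifest$rate_hz[i]))
}

#' Trim the edges of a recording
#'
#' Removes `floor(head_s * rate_hz)` leading and `floor(tail_s *
#' rate_hz)` trailing samples.  This is the programmatic counterpart of
#' the manual cleansing step that discards the "learning curve" at the
#' start and end of each recording, where the subject is settling into
#' (or out of) the activity.
#'
#' @param recording A `har_recording`.
#' @param head_s,tail_s Seconds to remove from each end (>= 0).
#' @return The trimmed `har_recording`.
#' @export
trim_recording <- function(recording, head_s = 0, tail_s = 0) {
  stopifnot(inherits(recording, "har_recording"))
  if (head_s < 0 || tail_s < 0) stop("trim durations must be >= 0")
  n <- nrow(recording$samples)
  nh <- floor(head_s * recording$rate_hz)
  nt <- floor(tail_s * recording$rate_hz)
  if (nh + nt >= n)
    stop("trim of ", nh + nt, " samples leaves nothing of a ", n,
         "-sample recording")
  recording$samples <- recording$samples[(nh + 1L):(n - nt), , drop = FALSE]
  # segment truth no longer aligned once samples are dropped
  if (nh > 0 || nt > 0) recording$contaminated_segments <- integer(0)
  recording
}

#' Segment a recording into non-overlapping windows
#'
#' Windows have a fixed length of `floor(window_s * rate_hz)` samples
#' (204 at the default 4 s and 51.2 Hz; the product 204.8 is floored so
#' no sample is ever fabricated).  The trailing partial window is
#' discarded.  A recording shorter than one window yields an empty list
#' with a message, not an error.
#'
#' @param recording A `har_recording`.
#' @param window_s Window length in seconds (> 0), default 4.
#' @return A list of `har_window` objects, each with the parent
#'   metadata, a 0-based `index` and an L x 3 `samples` matrix.
#' @export
window_recording <- function(recording, window_s = 4) {
  stopifnot(inherits(recording, "har_recording"))
  if (window_s <= 0) stop("`window_s` must be > 0")
  L <- floor(window_s * recording$rate_hz)
  if (L < 2L) stop("window of ", L, " samples is too short")
  n <- nrow(recording$samples)
  k <- floor(n / L)
  if (k == 0L) {
    message("recording ", recording$subject, "/", recording$activity,
            " shorter than one window; no windows produced")
    return(list())
  }
  lapply(seq_len(k) - 1L, function(i) {
    structure(list(subject = recording$subject,
                   activity = recording$activity,
                   index = i,
                   samples = recording$samples[(i * L + 1L):((i + 1L) * L), ,
                                               drop = FALSE]),
              class = "har_window")
  })
}

# Metadata columns that precede the feature block in a feature table.
meta_cols <- function() c("subject", "activity", "window")

#' Build a feature table from recordings
#'
#' Applies optional edge trimming, windows every recording, and
#' extracts the 51 per-window features.  Rows are windows; columns are
#' `subject`, `activity`, `window` (0-based index) followed by the 51
#' features of [feature_names()].
#'
#' @param recordings List of `har_recording` objects.
#' @param window_s Window length in seconds.
#' @param trim_head_s,trim_tail_s Seconds trimmed from each recording
#'   edge before windowing.
#' @return A data frame (a feature table).
#' @export
build_feature_table <- function(recordings, window_s = 4,
                                trim_head_s = 0, trim_tail_s = 0) {
  rows <- lapply(recordings, function(rec) {
    if (trim_head_s > 0 || trim_tail_s > 0)
      rec <- trim_recording(rec, trim_head_s, trim_tail_s)
    wins <- window_recording(rec, window_s)
    if (!length(wins)) return(NULL)
    feats <- t(vapply(wins, function(w)
      extract_features(w$samples, rec$rate_hz), numeric(51L)))
    cbind(data.frame(subject = rec$subject, activity = rec$activity,
                     window = vapply(wins, `[[`, numeric(1), "index"),
                     stringsAsFactors = FALSE),
          as.data.frame(feats))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a feature table as CSV
#'
#' Lossless round-trip of the 51 features plus metadata columns.
#' Reading validates the schema and names any missing column.
#'
#' @param table A feature table data frame.
#' @param path File path.
#' @export
write_feature_table <- function(table, path) {
  check_feature_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_feature_table(df)
  df
}

check_feature_table <- function(df) {
  need <- c(meta_cols(), feature_names())
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "))
  invisible(df)
}

#' Export a feature table as a Weka ARFF file
#'
#' Declares the 51 features as numeric attributes and the activity as a
#' nominal class attribute, so the table can be loaded directly into
#' Weka-style tools.  Subject and window metadata are not exported
#' (ARFF carries only model attributes).
#'
#' @param table A feature table data frame.
#' @param path Output path.
#' @param relation ARFF relation name.
#' @export
write_arff <- function(table, path, relation = "har_features") {
  check_feature_table(table)
  feats <- feature_names()
  classes <- sort(unique(table$activity))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@relation %s", relation), con)
  writeLines(sprintf("@attribute %s numeric", feats), con)
  writeLines(sprintf("@attribute class {%s}",
                     paste(classes, collapse = ",")), con)
  writeLines("@data", con)
  vals <- as.matrix(table[, feats])
  lines <- apply(vals, 1L, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = ","))
  writeLines(paste0(lines, ",", table$activity), con)
  invisible(path)
}
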