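#' Construct and validate a tri-axial acceleration recording
#'
#' An `accel_recording` holds one subject's continuous wrist acceleration
#' stream: an N x 3 matrix of accelerations in g (axis order X, Y, Z)
#' plus the sampling rate and a start time in seconds.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param sampling_rate Sampling rate in Hz (the study device runs at 32 Hz).
#' @param samples Numeric N x 3 matrix of accelerations in g.
#' @param start_time Recording start in seconds (default 0).
#' @return An object of class `accel_recording`.
#' @export
accel_recording <- function(subject_id, sampling_rate, samples, start_time = 0) {
  samples <- as.matrix(samples)
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stop("subject_id must be a non-empty character scalar", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("sampling_rate must be a positive number", call. = FALSE)
  if (ncol(samples) != 3L)
    stop("samples must have exactly 3 columns (X, Y, Z); got ", ncol(samples),
         call. = FALSE)
  if (nrow(samples) < 1L)
    stop("samples must contain at least one row", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("samples contain non-finite values", call. = FALSE)
  colnames(samples) <- AXES
  structure(
    list(subject_id = subject_id, sampling_rate = sampling_rate,
         start_time = start_time, samples = samples),
    class = "accel_recording"
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> subject %s: %d samples x 3 axes @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Construct and validate a task annotation track
#'
#' Annotations mark which task is being performed when: a set of
#' `(label, start_s, end_s)` intervals, in seconds relative to the
#' recording start. Intervals must be sorted, non-overlapping, and use
#' only the ten-task vocabulary in [TASK_LABELS].
#'
#' @param entries Data frame with columns `label`, `start_s`, `end_s`.
#' @return An object of class `annotation_track` (a validated data frame).
#' @export
annotation_track <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  req <- c("label", "start_s", "end_s")
  if (!all(req %in% names(entries)))
    stop("annotation entries need columns label, start_s, end_s", call. = FALSE)
  entries <- entries[, req]
  entries$label <- as.character(entries$label)
  bad <- setdiff(unique(entries$label), TASK_LABELS)
  if (length(bad))
    stop("unknown task label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(entries$start_s)) || any(!is.finite(entries$end_s)))
    stop("annotation times must be finite numbers", call. = FALSE)
  if (any(entries$start_s >= entries$end_s)) {
    i <- which(entries$start_s >= entries$end_s)[1L]
    stop(sprintf("annotation %d has start_s >= end_s (%g >= %g)",
                 i, entries$start_s[i], entries$end_s[i]), call. = FALSE)
  }
  if (is.unsorted(entries$start_s, strictly = TRUE))
    stop("annotation intervals must be sorted by start_s", call. = FALSE)
  if (nrow(entries) > 1L) {
    ov <- which(entries$start_s[-1L] < entries$end_s[-nrow(entries)])
    if (length(ov))
      stop(sprintf(
        "annotations %d and %d overlap: [%g, %g) and [%g, %g)",
        ov[1L], ov[1L] + 1L,
        entries$start_s[ov[1L]], entries$end_s[ov[1L]],
        entries$start_s[ov[1L] + 1L], entries$end_s[ov[1L] + 1L]),
        call. = FALSE)
  }
  rownames(entries) <- NULL
  class(entries) <- c("annotation_track", "data.frame")
  entries
}

# recording CSV dialect (modelled on wrist-device exports):
#   subject_id,<id>
#   sampling_rate,<hz>
#   start_time,<s>
#   x,y,z
#   <numeric rows...>

#' Write a recording to the plain-text CSV dialect
#'
#' @param rec An [accel_recording()].
#' @param path Destination file path.
#' @param digits Significant digits for sample values (default 8, so the
#'   read/write round trip is exact to well below 1e-6 g).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 8) {
  stopifnot(inherits(rec, "accel_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("subject_id,", rec$subject_id),
    paste0("sampling_rate,", format(rec$sampling_rate, digits = 15)),
    paste0("start_time,", format(rec$start_time, digits = 15)),
    "x,y,z"
  ), con)
  rows <- apply(signif(rec$samples, digits), 1L,
                function(r) paste(formatC(r, format = "g", digits = digits),
                                  collapse = ","))
  writeLines(rows, con)
  invisible(path)
}

parse_header_line <- function(lines, i, key, path) {
  if (length(lines) < i)
    stop(sprintf("%s: line %d: expected '%s,<value>' header, file ends", path, i, key),
         call. = FALSE)
  parts <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || parts[1L] != key)
    stop(sprintf("%s: line %d: expected '%s,<value>' header", path, i, key),
         call. = FALSE)
  parts[2L]
}

#' Read a recording from the plain-text CSV dialect
#'
#' @param path File path written by [write_recording()] (or any file in
#'   the same dialect). Parse errors report the offending line number.
#' @return An [accel_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  subject_id <- parse_header_line(lines, 1L, "subject_id", path)
  fs_txt <- parse_header_line(lines, 2L, "sampling_rate", path)
  fs <- suppressWarnings(as.numeric(fs_txt))
  if (is.na(fs))
    stop(sprintf("%s: line 2: non-numeric sampling_rate '%s'", path, fs_txt),
         call. = FALSE)
  if (fs <= 0)
    stop(sprintf("%s: line 2: sampling_rate must be positive, got %g", path, fs),
         call. = FALSE)
  t0_txt <- parse_header_line(lines, 3L, "start_time", path)
  t0 <- suppressWarnings(as.numeric(t0_txt))
  if (is.na(t0))
    stop(sprintf("%s: line 3: non-numeric start_time '%s'", path, t0_txt),
         call. = FALSE)
  if (length(lines) < 4L || lines[4L] != "x,y,z")
    stop(sprintf("%s: line 4: expected column header 'x,y,z'", path), call. = FALSE)
  body <- lines[-(1:4)]
  body <- body[nzchar(body)]
  if (!length(body))
    stop(sprintf("%s: no sample rows after line 4", path), call. = FALSE)
  fields <- strsplit(body, ",", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 3L)) {
    i <- which(ncols != 3L)[1L]
    stop(sprintf("%s: line %d: expected 3 columns, found %d", path, i + 4L, ncols[i]),
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) {
    i <- (which(is.na(vals))[1L] - 1L) %/% 3L + 1L
    stop(sprintf("%s: line %d: non-numeric cell", path, i + 4L), call. = FALSE)
  }
  samples <- matrix(vals, ncol = 3L, byrow = TRUE)
  accel_recording(subject_id, fs, samples, start_time = t0)
}

#' Write an annotation track as CSV
#'
#' @param track An [annotation_track()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  track <- annotation_track(track)
  utils::write.csv(as.data.frame(unclass(track), stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotation track from CSV
#'
#' Validates on read: interval ordering, non-overlap, and the ten-task
#' label vocabulary.
#'
#' @param path CSV with columns `label,start_s,end_s`.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  annotation_track(df)
}
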