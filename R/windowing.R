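#' Windowing configuration
#'
#' Non-overlapping fixed-length windows are the unit of classification.
#' The study uses 4 s and 10 s windows, i.e. 128 and 320 samples at
#' 32 Hz.
#'
#' @param window_s Window length in seconds (4 or 10 by convention;
#'   other values are permitted).
#' @param sampling_rate Hz.
#' @return An object of class `windowing_config` with the derived
#'   per-window sample count `L`.
#' @export
windowing_config <- function(window_s, sampling_rate = 32) {
  L <- window_s * sampling_rate
  if (window_s <= 0 || abs(L - round(L)) > 1e-9)
    stop("window_s x sampling_rate must be a positive integer", call. = FALSE)
  structure(list(window_s = window_s, sampling_rate = sampling_rate,
                 L = as.integer(round(L))),
            class = "windowing_config")
}

#' Segment an annotated recording into labelled windows
#'
#' Within each annotated interval, consecutive non-overlapping windows
#' are anchored at the interval start (the start is rounded up to the
#' next sample for deterministic indexing); a trailing partial window
#' is discarded. No window ever spans two annotation intervals, so
#' every window carries a single task label.
#'
#' @param rec An [accel_recording()].
#' @param track An [annotation_track()] whose times lie within the
#'   recording extent.
#' @param cfg A [windowing_config()]; its sampling rate must match the
#'   recording's.
#' @return List of `window` objects, each a list with `subject_id`,
#'   `label`, `start_s`, `window_s`, `sampling_rate` and an `L x 3`
#'   `samples` matrix. If every interval is shorter than the window, an
#'   empty list is returned with a warning.
#' @export
segment_windows <- function(rec, track, cfg) {
  stopifnot(inherits(rec, "accel_recording"), inherits(cfg, "windowing_config"))
  track <- annotation_track(track)
  if (abs(cfg$sampling_rate - rec$sampling_rate) > 1e-9)
    stop("windowing sampling_rate does not match the recording's", call. = FALSE)
  fs <- rec$sampling_rate
  N <- nrow(rec$samples)
  if (max(track$end_s) > N / fs + 1e-9)
    stop("annotation track extends beyond the recording", call. = FALSE)
  L <- cfg$L
  out <- list()
  for (i in seq_len(nrow(track))) {
    # 0-based first sample index, rounded up to the next sample
    first <- ceiling(track$start_s[i] * fs - 1e-9)
    last_excl <- floor(track$end_s[i] * fs + 1e-9)  # 0-based exclusive end
    n_avail <- last_excl - first
    nw <- max(0L, floor(n_avail / L))
    for (w in seq_len(nw)) {
      i0 <- first + (w - 1L) * L
      out[[length(out) + 1L]] <- structure(
        list(subject_id = rec$subject_id,
             label = track$label[i],
             start_s = i0 / fs,
             window_s = cfg$window_s,
             sampling_rate = fs,
             samples = rec$samples[(i0 + 1L):(i0 + L), , drop = FALSE]),
        class = "window")
    }
  }
  if (!length(out))
    warning("no interval is long enough for a ", cfg$window_s, " s window",
            call. = FALSE)
  out
}
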