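# Three per-window feature domains:
#   time     — order-4 low-pass Butterworth (fc 10 Hz) then 9 statistics
#              per axis: 27 features
#   freq     — FFT magnitudes of the raw axis signals at bins strictly
#              below 10 Hz (DC included): 3 x 10 x window_s features,
#              i.e. 120 (4 s) and 300 (10 s)
#   timefreq — db4 wavelet decomposition at the maximum admissible
#              level; entropy, zero- and mean-crossings plus the same 9
#              statistics per band: 3 x 12 x (level + 1) features,
#              i.e. 180 (4 s) and 216 (10 s)

STAT9_NAMES <- c("mean", "rms", "mad", "sd", "min", "max", "median", "p25", "p75")
BAND_DESCRIPTORS <- c("entropy", "zcross", "mcross", STAT9_NAMES)

#' Zero-lag-free low-pass Butterworth filter
#'
#' Order-4 low-pass Butterworth (bilinear transform via
#' [signal::butter()]), applied in a single forward pass so the
#' magnitude response keeps the textbook -3 dB gain at the cutoff.
#' Start-up transients are absorbed by an odd-reflection lead-in that
#' is discarded, so a constant signal passes through unchanged.
#'
#' Human movement at the wrist rarely exceeds 10 Hz, hence the default
#' cutoff; content above it is treated as noise for the time-domain
#' statistics.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param order Filter order (default 4).
#' @param fc Cutoff frequency in Hz (default 10); must be below `fs/2`.
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, fs, order = 4, fc = 10) {
  if (fc >= fs / 2)
    stop("cutoff fc must be below the Nyquist frequency fs/2", call. = FALSE)
  n <- length(x)
  if (n < 3 * order)
    stop("signal too short to filter (need >= ", 3 * order, " samples)",
         call. = FALSE)
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  pre <- min(n - 1L, 96L)
  lead <- 2 * x[1L] - x[(pre + 1L):2L]
  y <- as.numeric(signal::filter(bf, c(lead, x)))
  y[(pre + 1L):(pre + n)]
}

#' Nine summary statistics of a signal
#'
#' Mean, root mean square, mean absolute deviation (about the mean),
#' standard deviation (n-1 denominator), minimum, maximum, median, and
#' the 25th and 75th percentiles (linear interpolation).
#'
#' @param x Numeric vector, length >= 2.
#' @return Named numeric vector of length 9 (names
#'   `mean, rms, mad, sd, min, max, median, p25, p75`).
#' @export
stats9 <- function(x) {
  if (length(x) < 2L) stop("stats9 needs at least 2 samples", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mean(x),
    rms = sqrt(mean(x^2)),
    mad = mean(abs(x - mean(x))),
    sd = stats::sd(x),
    min = min(x),
    max = max(x),
    median = q[2L],
    p25 = q[1L],
    p75 = q[3L])
}

feature_vector <- function(values, domain, window_s) {
  structure(values, domain = domain, window_s = window_s,
            class = c("feature_vector", "numeric"))
}

check_window <- function(w) {
  if (!inherits(w, "window"))
    stop("expected a window object from segment_windows()", call. = FALSE)
  w
}

#' Time-domain features of a window (27 features)
#'
#' Each axis is low-pass filtered ([butterworth_lowpass()]) and
#' summarised by [stats9()]; the three axes are concatenated in X, Y, Z
#' order, giving exactly 27 features named `<axis>_<statistic>`.
#'
#' @param w A `window`.
#' @return A `feature_vector` with `domain = "time"`.
#' @export
time_features <- function(w) {
  check_window(w)
  vals <- unlist(lapply(seq_len(3L), function(j) {
    s <- stats9(butterworth_lowpass(w$samples[, j], w$sampling_rate))
    names(s) <- paste0(AXES[j], "_", STAT9_NAMES)
    s
  }))
  feature_vector(vals, "time", w$window_s)
}

freq_bin_names <- function(axis, k, window_s) {
  sprintf("%s_fft_%ghz", axis, k / window_s)
}

#' Frequency-domain features of a window (120 or 300 features)
#'
#' Per axis, the FFT of the raw (unfiltered) signal; the magnitudes of
#' bins with frequency strictly below 10 Hz (DC included) are retained,
#' i.e. `10 x window_s` bins per axis — 40 at 4 s and 100 at 10 s —
#' giving 120 and 300 features over the three axes. Names encode axis
#' and bin frequency, e.g. `y_fft_1.5hz`.
#'
#' @param w A `window`.
#' @return A `feature_vector` with `domain = "freq"`.
#' @export
freq_features <- function(w) {
  check_window(w)
  L <- nrow(w$samples)
  B <- as.integer(round(10 * w$window_s))  # bins k = 0..B-1, freq k / window_s
  vals <- unlist(lapply(seq_len(3L), function(j) {
    mag <- Mod(stats::fft(w$samples[, j]))[seq_len(B)]
    names(mag) <- freq_bin_names(AXES[j], 0:(B - 1L), w$window_s)
    mag
  }))
  feature_vector(vals, "freq", w$window_s)
}

#' Twelve descriptors of one wavelet coefficient band
#'
#' Shannon entropy of the normalised squared-coefficient distribution
#' (`p_i = c_i^2 / sum(c^2)`, natural log, 0 for an all-zero band), the
#' number of strict zero crossings, the number of strict mean crossings
#' (sign changes of `c - mean(c)`), and [stats9()].
#'
#' @param band Numeric coefficient vector, length >= 2.
#' @return Named numeric vector of length 12.
#' @export
band_features <- function(band) {
  if (length(band) < 2L) stop("band must have at least 2 coefficients", call. = FALSE)
  e2 <- band^2
  tot <- sum(e2)
  entropy <- if (tot <= 0) 0 else {
    p <- e2[e2 > 0] / tot
    -sum(p * log(p))
  }
  sgn <- sign(band)
  zc <- sum(sgn[-length(sgn)] * sgn[-1L] < 0)
  sgm <- sign(band - mean(band))
  mc <- sum(sgm[-length(sgm)] * sgm[-1L] < 0)
  c(entropy = entropy, zcross = zc, mcross = mc, stats9(band))
}

#' Time-frequency (wavelet) features of a window (180 or 216 features)
#'
#' Per axis, the raw signal is decomposed with [dwt_decompose()] at the
#' maximum admissible db4 level (4 for 128-sample, 5 for 320-sample
#' windows); [band_features()] is applied to the deepest approximation
#' band and every detail band. With 12 descriptors per band this gives
#' `3 x 12 x (level + 1)` features: 180 at 4 s and 216 at 10 s. Names
#' encode axis, band and descriptor, e.g. `z_cD3_entropy`.
#'
#' @param w A `window`.
#' @return A `feature_vector` with `domain = "timefreq"`.
#' @export
timefreq_features <- function(w) {
  check_window(w)
  vals <- unlist(lapply(seq_len(3L), function(j) {
    bands <- dwt_decompose(w$samples[, j])
    feats <- unlist(lapply(names(bands), function(bn) {
      f <- band_features(bands[[bn]])
      names(f) <- paste0(AXES[j], "_", bn, "_", BAND_DESCRIPTORS)
      f
    }))
    feats
  }))
  feature_vector(vals, "timefreq", w$window_s)
}

expected_dim <- function(domain, window_s, sampling_rate = 32) {
  L <- as.integer(round(window_s * sampling_rate))
  switch(domain,
         time = 27L,
         freq = 3L * as.integer(round(10 * window_s)),
         timefreq = 3L * 12L * (dwt_max_level(L) + 1L),
         stop("unknown feature domain: ", domain, call. = FALSE))
}

#' Assemble a feature matrix from windows
#'
#' Computes one feature domain for every window and stacks the vectors
#' (row order = input order), keeping per-row metadata (`subject_id`,
#' `label`, `start_s`) traceable to the source windows. All windows
#' must share one window length; the domain's dimension contract
#' (27 / 120 / 300 / 180 / 216) is enforced.
#'
#' @param windows Non-empty list of `window` objects.
#' @param domain One of `"time"`, `"freq"`, `"timefreq"`.
#' @return An object of class `feature_matrix`: list with `values`
#'   (numeric matrix with feature-name columns), `meta` (data frame),
#'   `domain`, `window_s`.
#' @export
build_feature_matrix <- function(windows, domain = c("time", "freq", "timefreq")) {
  domain <- match.arg(domain)
  if (!length(windows)) stop("no windows supplied", call. = FALSE)
  ws <- unique(vapply(windows, `[[`, 0, "window_s"))
  if (length(ws) != 1L)
    stop("windows mix lengths: ", paste(ws, collapse = ", "), call. = FALSE)
  fs <- windows[[1L]]$sampling_rate
  fun <- switch(domain, time = time_features, freq = freq_features,
                timefreq = timefreq_features)
  rows <- lapply(windows, fun)
  values <- do.call(rbind, lapply(rows, as.numeric))
  colnames(values) <- names(rows[[1L]])
  d_expect <- expected_dim(domain, ws, fs)
  if (ncol(values) != d_expect)
    stop("feature dimension ", ncol(values), " violates the ", domain,
         " contract (", d_expect, ")", call. = FALSE)
  meta <- data.frame(
    subject_id = vapply(windows, `[[`, "", "subject_id"),
    label = vapply(windows, `[[`, "", "label"),
    start_s = vapply(windows, `[[`, 0, "start_s"),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, meta = meta, domain = domain, window_s = ws,
                 sampling_rate = fs),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d %s features (%g s windows)\n",
              nrow(x$values), ncol(x$values), x$domain, x$window_s))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' The CSV has the metadata columns `subject_id,label,start_s` followed
#' by one column per feature name; `domain` and `window_s` travel in a
#' `# domain,window_s,sampling_rate` comment on the first line.
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @return `path` invisibly (write); a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s,%g,%g", fm$domain, fm$window_s, fm$sampling_rate), con)
  df <- cbind(fm$meta, as.data.frame(fm$values, check.names = FALSE))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  hdr <- strsplit(sub("^# ", "", readLines(path, n = 1L)), ",")[[1L]]
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE,
                        stringsAsFactors = FALSE)
  meta <- df[, c("subject_id", "label", "start_s")]
  values <- as.matrix(df[, -(1:3), drop = FALSE])
  structure(list(values = values, meta = meta, domain = hdr[1L],
                 window_s = as.numeric(hdr[2L]),
                 sampling_rate = as.numeric(hdr[3L])),
            class = "feature_matrix")
}
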