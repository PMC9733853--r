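# Orthogonal discrete wavelet transform with the Daubechies-4 (db4)
# mother wavelet (8-tap filters, 4 vanishing moments) and periodic
# ("periodization") boundary handling, so every level halves the band
# length exactly and the transform is orthogonal, giving perfect
# reconstruction. Implemented directly from the filter-bank recursion.

# db4 scaling (lowpass) filter h; sum(h) = sqrt(2), sum(h^2) = 1.
DB4_H <- c(
  0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
  -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
  0.032883011666885197, -0.010597401785069032
)
# quadrature-mirror highpass: g[m] = (-1)^m h[L-1-m]  (m = 0..L-1)
DB4_G <- (-1)^(0:7) * rev(DB4_H)

#' Maximum admissible db4 decomposition depth
#'
#' The deepest level at which the wavelet filter (length 8) still fits
#' the dyadically shortened signal:
#' `floor(log2(n_samples / (filter_length - 1)))`. For the study's
#' windows this gives 4 levels at 128 samples (4 s at 32 Hz) and 5
#' levels at 320 samples (10 s).
#'
#' @param n_samples Signal length in samples.
#' @return Integer decomposition depth (>= 1).
#' @export
dwt_max_level <- function(n_samples) {
  filter_len <- length(DB4_H)
  if (n_samples < filter_len)
    stop("signal too short for db4: need >= ", filter_len, " samples", call. = FALSE)
  lev <- floor(log2(n_samples / (filter_len - 1)))
  if (lev < 1)
    stop("no admissible decomposition level for ", n_samples, " samples", call. = FALSE)
  as.integer(lev)
}

# one analysis step with periodic wrap; x must have even length
dwt_step <- function(x) {
  n <- length(x)
  nh <- n %/% 2L
  a <- numeric(nh)
  d <- numeric(nh)
  base <- 2L * (seq_len(nh) - 1L)
  for (m in 0:7) {
    xi <- x[((base + m) %% n) + 1L]
    a <- a + DB4_H[m + 1L] * xi
    d <- d + DB4_G[m + 1L] * xi
  }
  list(a = a, d = d)
}

# one synthesis step (transpose of the orthogonal analysis operator)
idwt_step <- function(a, d) {
  nh <- length(a)
  n <- 2L * nh
  x <- numeric(n)
  base <- 2L * (seq_len(nh) - 1L)
  for (m in 0:7) {
    idx <- ((base + m) %% n) + 1L
    x[idx] <- x[idx] + DB4_H[m + 1L] * a + DB4_G[m + 1L] * d
  }
  x
}

#' Decompose a signal into db4 wavelet bands
#'
#' Repeatedly splits the approximation into approximation (cA) and
#' detail (cD) coefficients down to `level`. Periodization keeps every
#' band exactly half the length of its parent and the overall transform
#' orthogonal.
#'
#' @param x Numeric signal; its length must be divisible by `2^level`.
#' @param level Decomposition depth; defaults to [dwt_max_level()].
#' @return An object of class `wavelet_bands`: a list with elements
#'   `cA<L>`, `cD<L>`, ..., `cD1` (deepest first), plus attributes
#'   `level` and `n`.
#' @export
dwt_decompose <- function(x, level = dwt_max_level(length(x))) {
  n <- length(x)
  max_lev <- dwt_max_level(n)
  if (level > max_lev)
    stop("level ", level, " exceeds maximum admissible level ", max_lev, call. = FALSE)
  if (level < 1) stop("level must be >= 1", call. = FALSE)
  if (n %% 2^level != 0)
    stop("signal length ", n, " is not divisible by 2^level", call. = FALSE)
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    s <- dwt_step(a)
    a <- s$a
    details[[l]] <- s$d
  }
  bands <- c(list(a), rev(details))
  names(bands) <- c(paste0("cA", level), paste0("cD", level:1))
  structure(bands, level = level, n = n, class = "wavelet_bands")
}

#' Reconstruct a signal from db4 wavelet bands
#'
#' Inverse of [dwt_decompose()]. Bands may be zeroed (but not removed)
#' before reconstruction to isolate the signal content of particular
#' frequency bands, as done by [reconstruct_from_dwt()].
#'
#' @param bands A `wavelet_bands` object.
#' @return Numeric signal of the original length.
#' @export
dwt_reconstruct <- function(bands) {
  stopifnot(inherits(bands, "wavelet_bands"))
  level <- attr(bands, "level")
  a <- bands[[paste0("cA", level)]]
  for (l in level:1) {
    a <- idwt_step(a, bands[[paste0("cD", l)]])
  }
  a
}
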