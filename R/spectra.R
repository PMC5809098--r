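#' Averaged-periodogram (Welch) power spectral density
#'
#' Splits the series into overlapping segments, removes the mean of each
#' segment, applies a Hann window and averages the one-sided periodograms.
#' The estimate is scaled as a density (units^2/Hz) so that
#' \code{sum(power) * df} approximates the series variance (Parseval).
#'
#' @param x Numeric series (or \code{loop_ts}).
#' @param fs Sampling rate in Hz. Taken from \code{x$dt} when \code{x} is a
#'   \code{loop_ts}.
#' @param segment_length Samples per segment; default
#'   \code{min(floor(n/4), 2048)}.
#' @param overlap Fractional overlap between segments, default 0.5.
#' @param window \code{"hann"} (default) or \code{"rectangular"}.
#' @return A list of class \code{"spectrum_estimate"} with \code{freqs} (Hz),
#'   \code{power} (units^2/Hz) and \code{method} metadata.
#' @export
welch_psd <- function(x, fs = NULL, segment_length = NULL, overlap = 0.5,
                      window = c("hann", "rectangular")) {
  window <- match.arg(window)
  if (inherits(x, "loop_ts")) {
    if (is.null(fs)) fs <- 1 / x$dt
    x <- x$values
  }
  stopifnot(is.numeric(x), is.numeric(fs), fs > 0)
  n <- length(x)
  if (is.null(segment_length)) segment_length <- min(n %/% 4L, 2048L)
  segment_length <- as.integer(segment_length)
  if (segment_length < 8L || segment_length > n) {
    stop("series too short for segment_length = ", segment_length,
         call. = FALSE)
  }
  step <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  starts <- seq(1L, n - segment_length + 1L, by = step)
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(segment_length) / (segment_length + 1))
  } else rep(1, segment_length)
  u <- sum(w^2)
  nf <- segment_length %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment_length - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg)[seq_len(nf)])^2 / (fs * u)
    # one-sided: double everything except DC (and Nyquist when present)
    scale2 <- rep(2, nf); scale2[1L] <- 1
    if (segment_length %% 2L == 0L) scale2[nf] <- 1
    acc <- acc + p * scale2
  }
  structure(list(freqs = (seq_len(nf) - 1) * fs / segment_length,
                 power = acc / length(starts),
                 method = list(window = window,
                               segment_length = segment_length,
                               overlap = overlap, fs = fs,
                               n_segments = length(starts))),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %d frequencies 0..%.4g Hz (%s window, %d segments of %d)\n",
              length(x$freqs), max(x$freqs), x$method$window,
              x$method$n_segments, x$method$segment_length))
  invisible(x)
}

#' Frequency of the dominant spectral peak
#'
#' @param spec A \code{spectrum_estimate}.
#' @param f_min,f_max Restrict the search to this frequency range (Hz);
#'   defaults exclude only DC.
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(spec, f_min = 0, f_max = Inf) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  keep <- spec$freqs > f_min & spec$freqs <= f_max & spec$freqs > 0
  if (!any(keep)) stop("no frequency bins in the requested range", call. = FALSE)
  spec$freqs[keep][which.max(spec$power[keep])]
}

#' Mean power over a frequency band
#'
#' @param spec A \code{spectrum_estimate}.
#' @param band Numeric length-2 vector \code{c(f_lo, f_hi)} in Hz.
#' @param log Return \code{log10} of the band mean?
#' @return Scalar band power (or its log10).
#' @export
band_power <- function(spec, band, log = FALSE) {
  stopifnot(inherits(spec, "spectrum_estimate"),
            is.numeric(band), length(band) == 2L, band[1] < band[2])
  keep <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(keep)) {
    stop("band [", band[1], ", ", band[2], "] Hz contains no frequency bins",
         call. = FALSE)
  }
  out <- mean(spec$power[keep])
  if (log) log10(out) else out
}

#' Pearson correlation between two series
#' @param a,b Numeric vectors of equal length.
#' @return Correlation coefficient.
#' @export
pairwise_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Correlation matrix of a multichannel recording
#' @param multi Numeric matrix, time in rows, channels in columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(multi) {
  multi <- as.matrix(multi)
  if (any(apply(multi, 2L, stats::sd) == 0)) {
    stop("zero-variance channel", call. = FALSE)
  }
  stats::cor(multi)
}

#' Cross-correlogram of two series
#'
#' Pearson-normalized cross-correlation as a function of lag; the value at
#' zero lag equals the correlation coefficient. Positive lags mean \code{b}
#' lags behind \code{a} (a peak at lag L indicates \code{b} is a delayed copy
#' of \code{a}).
#'
#' @param a,b Numeric vectors of equal length.
#' @param max_lag Maximum lag in samples.
#' @param dt Optional sample interval; adds a \code{lag_time} column.
#' @return Data frame with \code{lag} (samples) and \code{value} columns.
#' @export
cross_correlogram <- function(a, b, max_lag, dt = NULL) {
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  cc <- stats::ccf(b, a, lag.max = max_lag, plot = FALSE,
                   demean = TRUE, type = "correlation")
  out <- data.frame(lag = as.numeric(cc$lag), value = as.numeric(cc$acf))
  if (!is.null(dt)) out$lag_time <- out$lag * dt
  out
}

#' Remove the mean of each gain block
#'
#' Subtracts the sample mean within each block of a partition of the series,
#' emulating the removal of gain-setting-dependent activity offsets before
#' filter estimation. Idempotent; total length is preserved.
#'
#' @param x Numeric series or matrix (time in rows).
#' @param boundaries Integer vector of block start indices. Must begin at 1,
#'   be strictly increasing and not exceed the series length.
#' @return Demeaned series/matrix of the same shape.
#' @export
block_demean <- function(x, boundaries = 1L) {
  mat <- is.matrix(x)
  xm <- if (mat) x else matrix(x, ncol = 1L)
  n <- nrow(xm)
  boundaries <- as.integer(boundaries)
  if (boundaries[1L] != 1L || is.unsorted(boundaries, strictly = TRUE) ||
      any(boundaries > n)) {
    stop("boundaries must be strictly increasing block start indices ",
         "beginning at 1 and <= length(x)", call. = FALSE)
  }
  ends <- c(boundaries[-1L] - 1L, n)
  if (any(ends < boundaries)) stop("empty block", call. = FALSE)
  for (k in seq_along(boundaries)) {
    idx <- boundaries[k]:ends[k]
    xm[idx, ] <- sweep(xm[idx, , drop = FALSE], 2L,
                       colMeans(xm[idx, , drop = FALSE]))
  }
  if (mat) xm else drop(xm)
}

#' Per-pair changes in correlation and low-frequency power between conditions
#'
#' For every pair of cells, computes the change (condition b minus condition
#' a) in pairwise correlation and the change in the pair's mean log10 band
#' power (the arithmetic mean of the two cells' log powers, i.e. the log of
#' the geometric mean). Also reports the Spearman rank correlation between
#' the two change measures across pairs.
#'
#' @param B_a,B_b Time-by-cell matrices for the two conditions (same cells).
#' @param fs Sampling rate (Hz).
#' @param band Frequency band for the power summary, default
#'   \code{c(0.01, 0.15)} Hz.
#' @param segment_length Passed to \code{\link{welch_psd}}.
#' @return Data frame with columns \code{cell_i}, \code{cell_j},
#'   \code{d_correlation}, \code{d_log_power}; the Spearman correlation is in
#'   the \code{"rank_correlation"} attribute.
#' @export
pairwise_change_metrics <- function(B_a, B_b, fs, band = c(0.01, 0.15),
                                    segment_length = NULL) {
  B_a <- as.matrix(B_a); B_b <- as.matrix(B_b)
  if (!identical(dim(B_a), dim(B_b))) {
    stop("conditions must share the same cells and length", call. = FALSE)
  }
  nc <- ncol(B_a)
  lp_a <- vapply(seq_len(nc), function(j)
    band_power(welch_psd(B_a[, j], fs, segment_length), band, log = TRUE),
    numeric(1))
  lp_b <- vapply(seq_len(nc), function(j)
    band_power(welch_psd(B_b[, j], fs, segment_length), band, log = TRUE),
    numeric(1))
  ca <- correlation_matrix(B_a)
  cb <- correlation_matrix(B_b)
  pairs <- which(upper.tri(ca), arr.ind = TRUE)
  out <- data.frame(
    cell_i = pairs[, 1L], cell_j = pairs[, 2L],
    d_correlation = cb[pairs] - ca[pairs],
    d_log_power = (lp_b[pairs[, 1L]] + lp_b[pairs[, 2L]]) / 2 -
      (lp_a[pairs[, 1L]] + lp_a[pairs[, 2L]]) / 2)
  if (nrow(out) >= 3L && stats::sd(out$d_correlation) > 0 &&
      stats::sd(out$d_log_power) > 0) {
    attr(out, "rank_correlation") <-
      stats::cor(out$d_correlation, out$d_log_power, method = "spearman")
  }
  out
}
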