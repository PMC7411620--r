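#' Electrodermal (GSR) statistical features
#'
#' Four time-domain statistics of a skin-conductance series: variance `V`
#' (population second central moment), Shannon entropy `E` of the 16-bin
#' equal-width histogram of signal values (natural log, 0*log 0 := 0),
#' kurtosis `K` and skewness `S`. Kurtosis defaults to the standard
#' dimensionless `m4/m2^2` (3 for a Gaussian); `literal_kurtosis = TRUE`
#' selects the raw `m4/m2` ratio instead. Skewness is `m3/m2^(3/2)`.
#'
#' A constant signal has `V = 0` and `E = 0`; its kurtosis and skewness are
#' undefined and are emitted as 0 with a warning.
#'
#' @param x Numeric series, length >= 32.
#' @param n_bins Histogram bins for the entropy estimate (default 16).
#' @param literal_kurtosis Use `m4/m2` instead of `m4/m2^2`.
#' @return Named vector `c(V, E, K, S)`.
#' @export
gsr_features <- function(x, n_bins = 16, literal_kurtosis = FALSE) {
  if (length(x) < 32) stop("GSR series too short (need >= 32 samples)")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  if (m2 == 0) {
    warning("constant signal: kurtosis and skewness undefined, emitted as 0")
    return(c(V = 0, E = 0, K = 0, S = 0))
  }
  brk <- seq(min(x), max(x), length.out = n_bins + 1)
  cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  p <- cnt / length(x)
  p <- p[p > 0]
  entropy <- -sum(p * log(p))
  k <- if (literal_kurtosis) m4 / m2 else m4 / m2^2
  c(V = m2, E = entropy, K = k, S = m3 / m2^1.5)
}

#' Detect systolic pulse peaks in a PPG signal
#'
#' Smooths (Savitzky-Golay), removes the slow baseline (1 s moving median of
#' the smoothed signal), then keeps local maxima with topographic prominence
#' of at least `prominence_sd` standard deviations of the detrended signal
#' and a minimum separation of `min_sep_s` seconds (higher peak wins).
#' On an optical pulse waveform the surviving maxima are the systolic
#' peaks, i.e. one per heart beat.
#'
#' @param ppg Numeric PPG series, at least 5 s long.
#' @param fs Sampling rate, Hz.
#' @param prominence_sd Prominence threshold in signal SDs (default 0.5).
#' @param min_sep_s Minimum peak separation in seconds (default 0.33,
#'   a refractory bound at 180 bpm).
#' @param smooth Logical; apply Savitzky-Golay smoothing first.
#' @return A `peak_train`: list with `idx` (1-based sample indices,
#'   ascending), `fs`, `duration_s`. May be empty.
#' @export
detect_pulse_peaks <- function(ppg, fs, prominence_sd = 0.5,
                               min_sep_s = 0.33, smooth = TRUE) {
  if (length(ppg) < 5 * fs) stop("PPG segment too short (need >= 5 s)")
  x <- if (smooth) savgol_smooth(ppg) else ppg
  base_w <- max(3L, round(fs) %/% 2L * 2L + 1L)  # ~1 s, odd
  baseline <- stats::runmed(x, base_w)
  x <- x - baseline
  n <- length(x)
  # a (near-)constant detrended signal has no pulse structure at all
  if (stats::sd(x) <= 1e-9 * max(abs(ppg), 1))
    return(structure(list(idx = integer(0), fs = fs,
                          duration_s = length(ppg) / fs),
                     class = "peak_train"))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  threshold <- prominence_sd * stats::sd(x)
  keep <- cand[vapply(cand, function(i) {
    peak_prominence(x, i, cand) >= threshold
  }, logical(1))]
  # enforce minimum separation, higher peak wins
  if (length(keep) > 1) {
    ord <- keep[order(-x[keep])]
    sel <- logical(0)
    chosen <- integer(0)
    min_gap <- round(min_sep_s * fs)
    for (i in ord) {
      if (!length(chosen) || all(abs(chosen - i) >= min_gap))
        chosen <- c(chosen, i)
    }
    keep <- sort(chosen)
  }
  structure(list(idx = keep, fs = fs, duration_s = length(ppg) / fs),
            class = "peak_train")
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles, where each saddle is the minimum between
# the peak and the nearest point that exceeds it (or the signal edge).
peak_prominence <- function(x, i, candidates = NULL) {
  h <- x[i]
  left_hi <- which(x[seq_len(i - 1)] > h)
  lo <- if (length(left_hi)) max(left_hi) + 1L else 1L
  left_base <- min(x[lo:i])
  right_hi <- which(x[(i + 1):length(x)] > h)
  hi <- if (length(right_hi)) i + min(right_hi) - 1L else length(x)
  right_base <- min(x[i:hi])
  h - max(left_base, right_base)
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train> %d peaks over %.1f s @ %g Hz\n",
              length(x$idx), x$duration_s, x$fs))
  invisible(x)
}

#' Heart rate from a pulse-peak train
#'
#' `(n_peaks - 1)` beats over the span between first and last peak,
#' expressed in beats per minute.
#'
#' @param peaks A `peak_train` with at least 2 peaks.
#' @return Heart rate, bpm.
#' @export
heart_rate <- function(peaks) {
  if (length(peaks$idx) < 2) stop("need >= 2 peaks to estimate heart rate")
  span_s <- (peaks$idx[length(peaks$idx)] - peaks$idx[1]) / peaks$fs
  (length(peaks$idx) - 1) / span_s * 60
}

#' Mean inter-beat interval (HRV)
#'
#' In this pipeline heart-rate variability is summarized as the mean time
#' interval between successive pulse peaks, in milliseconds. The standard
#' deviation of the intervals (SDNN) is attached as attribute `"sdnn"` as a
#' secondary output; it is not part of the 36-feature vector.
#'
#' @param peaks A `peak_train` with at least 2 peaks.
#' @return Mean inter-beat interval, ms.
#' @export
hrv <- function(peaks) {
  if (length(peaks$idx) < 2) stop("need >= 2 peaks to compute intervals")
  ibi_ms <- diff(peaks$idx) / peaks$fs * 1000
  structure(mean(ibi_ms), sdnn = stats::sd(ibi_ms))
}
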