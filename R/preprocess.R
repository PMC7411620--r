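#' Canonical EEG frequency bands
#'
#' Conventional five-band decomposition: delta 1-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-45 Hz. Bands are half-open `[low, high)` so adjacent
#' bands never double-count a frequency bin.
#'
#' @return Data frame with columns `band`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(
    band    = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz  = c(1, 4, 8, 13, 30),
    high_hz = c(4, 8, 13, 30, 45)
  )
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing, the standard pre-processing step
#' for consumer-grade physiological recordings: it suppresses broadband
#' sensor noise while preserving waveform morphology (in particular PPG
#' systolic peaks) because polynomials up to `polyorder` pass through
#' unchanged. Boundary samples are handled by the filter's startup/end
#' projection so the output has the same length as the input.
#'
#' @param x Numeric sample series.
#' @param window_len Odd window length in samples (default 31, about 0.12 s
#'   at 256 Hz).
#' @param polyorder Polynomial order (default 3); must be < `window_len`.
#' @return Smoothed series, same length as `x`.
#' @export
savgol_smooth <- function(x, window_len = 31, polyorder = 3) {
  if (window_len %% 2 == 0) stop("window_len must be odd")
  if (polyorder >= window_len) stop("polyorder must be smaller than window_len")
  if (length(x) < window_len) stop("signal shorter than the smoothing window")
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window_len))
}

# One-sided Welch PSD: Hann-windowed, mean-detrended segments with 50%
# overlap, averaged. Returns density in units^2/Hz on the grid 0..fs/2.
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  nseg <- round(seg_s * fs)
  if (length(x) < nseg) stop("signal shorter than one Welch segment")
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1)))
  U <- sum(w^2)
  nfreq <- nseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 / (fs * U)
    p <- p[seq_len(nfreq)]
    # fold negative frequencies into the one-sided density
    scale <- rep(2, nfreq)
    scale[1] <- 1
    if (nseg %% 2 == 0) scale[nfreq] <- 1
    acc <- acc + p * scale
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nseg, psd = acc / length(starts))
}

#' Band power of a signal
#'
#' Integrates the Welch averaged-periodogram power spectral density over a
#' frequency band `[low_hz, high_hz)`. With EEG in microvolts the result is
#' in uV^2. By Parseval's relation the five canonical band powers of a
#' 1-45 Hz band-limited signal sum to (approximately) its variance.
#'
#' @param x Numeric sample series, at least `seg_s` seconds long.
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Band edges; must satisfy 0 < low < high <= fs/2.
#' @param seg_s Welch segment length in seconds (default 2, 50% overlap,
#'   Hann window).
#' @return Nonnegative scalar power.
#' @export
band_power <- function(x, fs, low_hz, high_hz, seg_s = 2) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz <= fs / 2))
    stop("band must satisfy 0 < low_hz < high_hz <= fs/2")
  p <- welch_psd(x, fs, seg_s = seg_s)
  sel <- p$freq >= low_hz & p$freq < high_hz
  df <- p$freq[2] - p$freq[1]
  sum(p$psd[sel]) * df
}

#' Sliding-window band-power series
#'
#' Band power computed in sliding windows, producing the per-hemisphere
#' power time course whose left/right Pearson correlation is the EEG
#' correlation feature. Window positions are `floor((n - window) / hop) + 1`.
#'
#' @inheritParams band_power
#' @param window_s Window length in seconds (default 2).
#' @param hop_s Hop between window starts in seconds (default 1).
#' @return Numeric vector of band powers, one per window position.
#' @export
windowed_band_power <- function(x, fs, low_hz, high_hz,
                                window_s = 2, hop_s = 1) {
  nwin <- round(window_s * fs)
  nhop <- max(1L, round(hop_s * fs))
  if (length(x) < nwin) stop("signal shorter than one window")
  starts <- seq(1L, length(x) - nwin + 1L, by = nhop)
  vapply(starts, function(s) {
    band_power(x[s:(s + nwin - 1L)], fs, low_hz, high_hz,
               seg_s = min(window_s, 2))
  }, numeric(1))
}
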