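#' Rational asymmetry (RASM)
#'
#' Ratio of right- to left-hemisphere band power for a symmetric electrode
#' pair, `RASM = PR / PL`. Frontal alpha asymmetry in particular tracks the
#' valence of an affective stimulus.
#'
#' @param p_right,p_left Band powers (uV^2); `p_left` must be positive.
#' @return `p_right / p_left`.
#' @export
rasm <- function(p_right, p_left) {
  if (any(p_left <= 0)) stop("degenerate input: left-hemisphere power must be > 0")
  if (any(p_right < 0)) stop("powers must be nonnegative")
  p_right / p_left
}

#' Differential asymmetry (DASM)
#'
#' Right minus left hemispheric band power, `DASM = PR - PL` (uV^2).
#'
#' @param p_right,p_left Nonnegative band powers.
#' @return `p_right - p_left`.
#' @export
dasm <- function(p_right, p_left) {
  if (any(p_right < 0) || any(p_left < 0)) stop("powers must be nonnegative")
  p_right - p_left
}

#' Inter-hemispheric band-power correlation
#'
#' Pearson product-moment correlation between the right- and left-channel
#' windowed band-power series of a symmetric electrode pair.
#'
#' @param series_right,series_left Equal-length numeric series (length >= 3)
#'   with nonzero variance.
#' @return Correlation in \[-1, 1\].
#' @export
band_correlation <- function(series_right, series_left) {
  if (length(series_right) != length(series_left))
    stop("series must have equal length")
  if (length(series_right) < 3) stop("series too short (need >= 3)")
  if (stats::sd(series_right) == 0 || stats::sd(series_left) == 0)
    stop("degenerate input: zero-variance band-power series")
  stats::cor(series_right, series_left)
}

# Symmetric electrode pairs; 10-20 convention: odd index = left hemisphere.
electrode_pairs <- function() {
  data.frame(region = c("frontal", "temporal"),
             left = c("AF7", "TP9"), right = c("AF8", "TP10"))
}

#' Canonical EEG feature names
#'
#' 30 names: pair-major (frontal then temporal), band-minor (delta..gamma),
#' feature-minor (rasm, dasm, cb), e.g. `frontal_alpha_rasm`.
#'
#' @return Character vector of length 30.
#' @export
eeg_feature_names <- function() {
  pairs <- electrode_pairs()$region
  bands <- eeg_bands()$band
  feats <- c("rasm", "dasm", "cb")
  as.vector(vapply(pairs, function(p)
    vapply(bands, function(b) paste(p, b, feats, sep = "_"),
           character(3)), matrix("", 3, 5)))
}

#' Extract the 30 EEG features of a session
#'
#' For each symmetric electrode pair ((AF7, AF8) frontal, (TP9, TP10)
#' temporal) and each of the five canonical bands, computes RASM and DASM
#' from whole-epoch Welch band powers and the inter-hemispheric correlation
#' Cb from sliding-window band-power series (2 s window, 1 s hop). Channels
#' are Savitzky-Golay smoothed first.
#'
#' @param recording A `session_recording` with the four EEG channels.
#' @param savgol_window,savgol_order Smoothing parameters, see
#'   [savgol_smooth()].
#' @param window_s,hop_s Window/hop (s) for the correlation series.
#' @return Named numeric vector of length 30 in canonical order
#'   ([eeg_feature_names()]).
#' @export
extract_eeg_features <- function(recording, savgol_window = 31,
                                 savgol_order = 3, window_s = 2, hop_s = 1) {
  sig <- recording$signals
  stopifnot(all(c("TP9", "AF7", "AF8", "TP10") %in% names(sig)))
  fs <- recording$fs
  smoothed <- lapply(sig[c("TP9", "AF7", "AF8", "TP10")], savgol_smooth,
                     window_len = savgol_window, polyorder = savgol_order)
  pairs <- electrode_pairs()
  bands <- eeg_bands()
  out <- numeric(0)
  for (pi in seq_len(nrow(pairs))) {
    xl <- smoothed[[pairs$left[pi]]]
    xr <- smoothed[[pairs$right[pi]]]
    for (bi in seq_len(nrow(bands))) {
      lo <- bands$low_hz[bi]; hi <- bands$high_hz[bi]
      pr <- band_power(xr, fs, lo, hi)
      pl <- band_power(xl, fs, lo, hi)
      sr <- windowed_band_power(xr, fs, lo, hi, window_s, hop_s)
      sl <- windowed_band_power(xl, fs, lo, hi, window_s, hop_s)
      out <- c(out, rasm(pr, pl), dasm(pr, pl), band_correlation(sr, sl))
    }
  }
  names(out) <- eeg_feature_names()
  out
}
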