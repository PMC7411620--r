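#' Synthetic-study configuration
#'
#' Defines the acquisition layout and the per-emotion generative parameters
#' of the synthetic multimodal study: 21 participants each viewing 4 clips
#' (58, 35, 21 and 55 s) while 4 EEG channels (TP9, AF7, AF8, TP10, uV),
#' one GSR channel (uS) and one PPG channel (arbitrary units) are sampled at
#' 256 Hz. Emotion conditions modulate the signals the way affective
#' physiology does at the feature level: valence sets the right/left
#' hemispheric alpha-power ratio (> 1 for positive valence), arousal sets
#' the skin-conductance-response rate, the mean heart rate and the
#' inter-beat jitter (higher arousal: faster, more regular heart beat).
#'
#' By default emotion conditions are assigned with fixed class counts of
#' 9 relaxed, 22 sad, 40 happy and 13 angry sessions (84 total); set
#' `assignment = "sample"` to draw i.i.d. from `weights` instead.
#'
#' @param n_participants Number of participants (default 21).
#' @param clip_durations_s Clip lengths in seconds (default c(58, 35, 21, 55)).
#' @param fs Sampling rate in Hz (default 256).
#' @param assignment `"fixed"` (exact class counts) or `"sample"`.
#' @param class_counts Named counts per emotion, canonical order, used when
#'   `assignment = "fixed"`; must sum to `n_participants * length(clips)`.
#' @param weights Sampling weights per emotion (sum 1), used for `"sample"`.
#' @param emotion_params Data frame of per-emotion generative parameters;
#'   see Details for columns. Defaults encode the modulation above.
#' @param noise_sd Named list of additive white-noise SDs per modality
#'   (`eeg` uV, `gsr` uS, `ppg` a.u.).
#' @param master_seed Integer master seed; every per-session seed is derived
#'   from it deterministically.
#'
#' @details `emotion_params` columns: `emotion`; `valence_mean`,
#' `arousal_mean` (1-9 SAM scale); `alpha_gain` (right/left alpha band-power
#' ratio); `scr_rate` (skin-conductance responses per minute); `hr_mean`
#' (bpm, must lie in (30, 200)); `ibi_jitter_sd` (inter-beat-interval jitter
#' SD, ms).
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 21,
                         clip_durations_s = c(58, 35, 21, 55),
                         fs = 256,
                         assignment = c("fixed", "sample"),
                         class_counts = c(relaxed = 9, sad = 22,
                                          happy = 40, angry = 13),
                         weights = NULL,
                         emotion_params = default_emotion_params(),
                         noise_sd = list(eeg = 2, gsr = 0.01, ppg = 0.05),
                         master_seed = 1L) {
  assignment <- match.arg(assignment)
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (any(clip_durations_s <= 0)) stop("all clip durations must be > 0")
  if (fs <= 0) stop("fs must be > 0")
  stopifnot(setequal(emotion_params$emotion, emotion_levels()))
  if (any(emotion_params$valence_mean < 1 | emotion_params$valence_mean > 9) ||
      any(emotion_params$arousal_mean < 1 | emotion_params$arousal_mean > 9))
    stop("valence/arousal means must lie in [1, 9]")
  if (any(emotion_params$hr_mean <= 30 | emotion_params$hr_mean >= 200))
    stop("hr_mean must lie in (30, 200)")
  n_sessions <- n_participants * length(clip_durations_s)
  if (assignment == "fixed") {
    if (!setequal(names(class_counts), emotion_levels()))
      stop("class_counts must be named by the four emotions")
    class_counts <- class_counts[emotion_levels()]
    if (sum(class_counts) != n_sessions)
      stop("class_counts must sum to n_participants * n_clips (",
           n_sessions, ")")
  } else {
    if (is.null(weights)) weights <- rep(0.25, 4)
    if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    clip_durations_s = clip_durations_s,
    fs = fs,
    assignment = assignment,
    class_counts = class_counts,
    weights = weights,
    emotion_params = emotion_params,
    noise_sd = noise_sd,
    master_seed = as.integer(master_seed)
  ), class = "synth_config")
}

#' Default per-emotion generative parameters
#'
#' Positive-valence conditions get right-dominant alpha (ratio 1.8), negative
#' valence left-dominant (0.55). High-arousal conditions get 6 SCR/min,
#' 78 bpm and 20 ms inter-beat jitter; low-arousal 2 SCR/min, 64 bpm, 45 ms.
#'
#' @return Data frame, one row per emotion in canonical order.
#' @export
default_emotion_params <- function() {
  data.frame(
    emotion       = c("relaxed", "sad", "happy", "angry"),
    valence_mean  = c(7, 3, 7, 3),
    arousal_mean  = c(3, 3, 7, 7),
    alpha_gain    = c(1.8, 0.55, 1.8, 0.55),
    scr_rate      = c(2, 2, 6, 6),
    hr_mean       = c(64, 64, 78, 78),
    ibi_jitter_sd = c(45, 45, 20, 20)
  )
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic per-session seed, kept inside 32-bit integer range.
session_seed <- function(master_seed, p_index, c_index) {
  as.integer((as.double(master_seed) * 48271 + p_index * 7919 +
                c_index * 104729) %% 2147483647)
}

# Band-limited unit-variance noise: white noise filtered by an ideal
# frequency-domain brick-wall on [low_hz, high_hz), so each band's power is
# exactly controllable (no transition-band bleed between adjacent bands).
band_noise <- function(n, fs, low_hz, high_hz) {
  f <- stats::fft(stats::rnorm(n))
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # fold to two-sided magnitudes
  f[!(freqs >= low_hz & freqs < high_hz)] <- 0
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Baseline EEG band powers (uV^2), a rough 1/f profile. Alpha power on
# right-hemisphere channels is multiplied by the emotion's alpha_gain.
eeg_band_power_profile <- function() {
  c(delta = 20, theta = 10, alpha = 8, beta = 4, gamma = 2)
}

# Bi-exponential skin-conductance-response kernel (rise 0.75 s, decay 2 s),
# normalized to unit peak.
scr_kernel <- function(fs, rise_s = 0.75, decay_s = 2, len_s = 10) {
  t <- seq(0, len_s, by = 1 / fs)
  h <- exp(-t / decay_s) - exp(-t / rise_s)
  h / max(h)
}

# Single PPG pulse: systolic peak plus a smaller, later dicrotic bump.
ppg_pulse <- function(t_rel) {
  exp(-0.5 * (t_rel / 0.06)^2) + 0.25 * exp(-0.5 * ((t_rel - 0.25) / 0.09)^2)
}

draw_sam_rating <- function(v_mean, a_mean, emotion, midpoint = 5) {
  repeat {
    v <- round(stats::rnorm(1, v_mean, 1))
    a <- round(stats::rnorm(1, a_mean, 1))
    v <- min(max(v, 1), 9)
    a <- min(max(a, 1), 9)
    if (v == midpoint || a == midpoint) next
    if (as.character(label_emotion(v, a, midpoint)) == emotion)
      return(c(valence = v, arousal = a))
  }
}

#' Generate one synthetic session
#'
#' Produces a multimodal recording with known ground truth for one
#' participant x clip under a given emotion condition. Identical
#' `(config, ids, emotion, seed)` give bit-identical output.
#'
#' Signal models: EEG channels are mixtures of per-band band-limited noise
#' (Butterworth-filtered white noise scaled to a 1/f-like band-power
#' profile) with a shared within-band component across channels so
#' hemispheric band-power series correlate; the alpha band on right
#' channels (AF8, TP10) carries `alpha_gain` times the left-channel power.
#' GSR is a slow tonic drift plus Poisson-arriving phasic responses
#' convolved with a bi-exponential kernel (0.75 s rise, 2 s decay). PPG is
#' a pulse train at `hr_mean` bpm with Gaussian inter-beat jitter, plus
#' baseline wander. White measurement noise is added per modality.
#'
#' @param config A [synth_config()].
#' @param participant Participant index (1-based).
#' @param clip Clip index (1-based).
#' @param emotion One of `emotion_levels()`.
#' @param seed Integer seed for this session; defaults to a deterministic
#'   function of the config's master seed and the indices.
#' @return List with `recording` (class `session_recording`: ids, `fs`,
#'   `n_samples` and a `signals` data frame with columns `t_s`, `TP9`,
#'   `AF7`, `AF8`, `TP10`, `GSR`, `PPG`) and `truth` (class `ground_truth`:
#'   emotion, SAM rating, true `hr_mean`, `scr_rate`, `alpha_gain`, realized
#'   SCR event and heart-beat counts).
#' @export
generate_session <- function(config, participant, clip, emotion,
                             seed = session_seed(config$master_seed,
                                                 participant, clip)) {
  if (!emotion %in% emotion_levels())
    stop("unknown emotion label: ", emotion)
  duration <- config$clip_durations_s[clip]
  if (is.na(duration) || duration <= 0) stop("non-positive clip duration")
  fs <- config$fs
  n <- round(duration * fs)
  pars <- config$emotion_params[config$emotion_params$emotion == emotion, ]

  with_local_seed(seed, {
  t_s <- (seq_len(n) - 1) / fs

  # --- EEG: per-band shared + private noise, alpha gain on the right ---
  bands <- eeg_bands()
  profile <- eeg_band_power_profile()
  channels <- c("TP9", "AF7", "AF8", "TP10")
  right <- c(FALSE, FALSE, TRUE, TRUE)
  eeg <- matrix(0, nrow = n, ncol = 4, dimnames = list(NULL, channels))
  rho_shared <- 0.7  # variance fraction of the pair-shared band component
  for (b in seq_len(nrow(bands))) {
    shared <- band_noise(n, fs, bands$low_hz[b], bands$high_hz[b])
    for (ch in 1:4) {
      own <- band_noise(n, fs, bands$low_hz[b], bands$high_hz[b])
      mix <- sqrt(rho_shared) * shared + sqrt(1 - rho_shared) * own
      pw <- profile[[bands$band[b]]]
      if (bands$band[b] == "alpha" && right[ch]) pw <- pw * pars$alpha_gain
      # renormalize so each channel's band power hits its target exactly
      eeg[, ch] <- eeg[, ch] + mix / stats::sd(mix) * sqrt(pw)
    }
  }
  eeg <- eeg + matrix(stats::rnorm(n * 4, sd = config$noise_sd$eeg), n, 4)

  # --- GSR: tonic drift + Poisson phasic responses ---
  tonic <- 2 + 0.2 * sin(2 * pi * 0.01 * t_s + stats::runif(1, 0, 2 * pi)) +
    0.05 * t_s / duration
  n_scr <- stats::rpois(1, pars$scr_rate / 60 * duration)
  phasic <- numeric(n)
  if (n_scr > 0) {
    kern <- scr_kernel(fs)
    onsets <- sort(stats::runif(n_scr, 0, max(duration - 1, 0.5)))
    amps <- stats::rlnorm(n_scr, meanlog = log(0.3), sdlog = 0.3)
    for (i in seq_len(n_scr)) {
      i0 <- round(onsets[i] * fs) + 1L
      idx <- i0:min(n, i0 + length(kern) - 1L)
      phasic[idx] <- phasic[idx] + amps[i] * kern[seq_along(idx)]
    }
  }
  gsr <- tonic + phasic + stats::rnorm(n, sd = config$noise_sd$gsr)

  # --- PPG: jittered pulse train + baseline wander ---
  ibi_mean <- 60 / pars$hr_mean
  beat_t <- stats::runif(1, 0, ibi_mean)
  beats <- numeric(0)
  while (beat_t < duration) {
    beats <- c(beats, beat_t)
    beat_t <- beat_t + ibi_mean +
      stats::rnorm(1, sd = pars$ibi_jitter_sd / 1000)
  }
  ppg <- 0.2 * sin(2 * pi * 0.25 * t_s + stats::runif(1, 0, 2 * pi))
  for (tb in beats) {
    idx <- which(t_s >= tb - 0.4 & t_s <= tb + 0.6)
    ppg[idx] <- ppg[idx] + ppg_pulse(t_s[idx] - tb)
  }
  ppg <- ppg + stats::rnorm(n, sd = config$noise_sd$ppg)

  sam <- draw_sam_rating(pars$valence_mean, pars$arousal_mean, emotion)

  recording <- structure(list(
    participant_id = participant, clip_id = clip, fs = fs, n_samples = n,
    signals = data.frame(t_s = t_s, TP9 = eeg[, 1], AF7 = eeg[, 2],
                         AF8 = eeg[, 3], TP10 = eeg[, 4],
                         GSR = gsr, PPG = ppg)
  ), class = "session_recording")
  truth <- structure(list(
    participant_id = participant, clip_id = clip, emotion = emotion,
    valence = unname(sam["valence"]), arousal = unname(sam["arousal"]),
    hr_mean = pars$hr_mean, scr_rate = pars$scr_rate,
    alpha_gain = pars$alpha_gain, ibi_jitter_sd = pars$ibi_jitter_sd,
    n_scr_events = n_scr, n_beats = length(beats), seed = seed
  ), class = "ground_truth")
  list(recording = recording, truth = truth)
  })
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> participant %s, clip %s: %d samples @ %g Hz (%.1f s)\n",
    x$participant_id, x$clip_id, x$n_samples, x$fs, x$n_samples / x$fs))
  invisible(x)
}

#' Generate the full synthetic dataset
#'
#' Generates every participant x clip session under the configured emotion
#' assignment. With defaults this is 21 x 4 = 84 sessions with exact class
#' counts 9 relaxed / 22 sad / 40 happy / 13 angry. Regeneration under the
#' same `master_seed` is bit-identical.
#'
#' @param config A [synth_config()].
#' @return List with `recordings` (list of `session_recording`), `truths`
#'   (list of `ground_truth`) and `manifest` (data frame: one row per
#'   session with ids, seed, emotion condition, SAM rating and the true
#'   generative parameters).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_clips <- length(config$clip_durations_s)
  n_sessions <- config$n_participants * n_clips
  emotions <- with_local_seed(config$master_seed, {
    if (config$assignment == "fixed")
      sample(rep(emotion_levels(), times = config$class_counts))
    else
      sample(emotion_levels(), n_sessions, replace = TRUE,
             prob = config$weights)
  })
  recordings <- vector("list", n_sessions)
  truths <- vector("list", n_sessions)
  i <- 0L
  for (p in seq_len(config$n_participants)) {
    for (cl in seq_len(n_clips)) {
      i <- i + 1L
      out <- generate_session(config, p, cl, emotions[i])
      recordings[[i]] <- out$recording
      truths[[i]] <- out$truth
    }
  }
  manifest <- do.call(rbind, lapply(truths, function(tr) {
    data.frame(participant = tr$participant_id, clip = tr$clip_id,
               seed = tr$seed, emotion = tr$emotion,
               valence = tr$valence, arousal = tr$arousal,
               hr_mean = tr$hr_mean, scr_rate = tr$scr_rate,
               alpha_gain = tr$alpha_gain,
               n_scr_events = tr$n_scr_events, n_beats = tr$n_beats)
  }))
  manifest$session <- seq_len(n_sessions)
  list(recordings = recordings, truths = truths, manifest = manifest)
}
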