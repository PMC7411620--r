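---
title: "Methods: multimodal physiological emotion recognition in affectfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal physiological emotion recognition in affectfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

affectfuse implements a complete pipeline for recognizing four
Russell-quadrant emotions — happy, angry, sad, relaxed — from three
wearable physiological modalities recorded while a participant experiences
affective multimedia content: four-channel EEG (TP9, AF7, AF8, TP10, the
electrode montage of consumer headbands), skin conductance (GSR) from a
finger electrode, and an ear-lobe photoplethysmogram (PPG), all sampled at
256 Hz. Each of 21 participants views 4 clips (58, 35, 21 and 55 s), giving
84 sessions; after each clip the participant reports valence and arousal on
9-point Self-Assessment Manikin (SAM) scales.

Since no recordings of this design are publicly available, the package
ships a first-class synthetic generator that emulates the acquisition with
emotion-dependent signal structure, so every downstream stage — smoothing,
band-power estimation, feature extraction, labeling, fusion,
classification, evaluation — is testable end to end, and the evaluation
module is additionally verified against published benchmark confusion
matrices bundled with the package.

## Labeling: Russell quadrants of SAM space

A session's label is the quadrant of its (valence, arousal) rating around
the scale midpoint 5: high valence & high arousal = happy, low/high =
angry, low/low = sad, high/low = relaxed. Ratings exactly at the midpoint
are assigned to the *low* side. This tie policy is a documented convention:
the generator resamples any drawn rating that lands on 5, so no synthetic
session ever depends on it. The canonical class order everywhere in the
package (factors, probability vectors, confusion matrices) is relaxed,
sad, happy, angry.

## The synthetic generator

`synth_config()` fixes the study conditions; `generate_dataset()` realizes
them. Defaults are the acquisition layout above with exact class counts
9 relaxed / 22 sad / 40 happy / 13 angry (84 sessions); i.i.d. sampling
from weights is available as an alternative assignment mode.

Per-emotion generative parameters (defaults in
`default_emotion_params()`) encode the standard directional findings of
affective physiology rather than any particular dataset:

* **Valence → hemispheric alpha asymmetry.** Each EEG channel is a mixture
  of per-band band-limited noise (white noise brick-wall filtered in the
  frequency domain, so each band's power is exactly controllable) scaled
  to a 1/f-like profile (delta 20, theta 10, alpha 8, beta 4, gamma 2
  uV^2). Right-hemisphere channels (AF8, TP10) carry `alpha_gain` times
  the left alpha power: 1.8 for positive-valence conditions, 0.55 for
  negative. Within each band, 70% of each channel's variance is a
  pair-shared component so left/right band-power series correlate, as
  hemispheric EEG power does.
* **Arousal → electrodermal activity.** GSR is a ~2 uS tonic level with
  slow drift plus phasic skin-conductance responses arriving as a Poisson
  process (6/min under high arousal, 2/min under low), each convolved with
  a bi-exponential kernel (0.75 s rise, 2 s decay) with log-normal
  amplitudes around 0.3 uS.
* **Arousal → cardiac dynamics.** PPG is a pulse train (Gaussian systolic
  peak plus a smaller dicrotic bump) at 78 bpm under high arousal with
  20 ms inter-beat jitter, versus 64 bpm with 45 ms jitter under low
  arousal, over 0.25 Hz baseline wander.

SAM ratings are drawn from normal distributions (sd 1) around per-emotion
centers (7, 7), (3, 7), (3, 3), (7, 3), rounded, clipped to [1, 9], and
resampled if they hit the midpoint or the wrong quadrant — so ground-truth
conditions and quadrant labels agree by construction.

Determinism: each session's seed is a fixed arithmetic function of the
master seed and the (participant, clip) indices, so datasets regenerate
bit-identically; all seeding uses a save/restore wrapper that leaves the
caller's RNG stream untouched.

What the generator does **not** emulate: volume-conducted source mixing,
eye-blink/EMG artifacts, movement, respiratory coupling, or inter-subject
variability in baseline physiology. Passing tests demonstrate that the
pipeline recovers what the generator encodes — not that these features
suffice on real recordings.

## Pre-processing

All modalities are smoothed with a Savitzky–Golay filter, default window
31 samples (~0.12 s at 256 Hz), polynomial order 3, same-length output
with polynomial boundary handling. Polynomials up to the order pass
through exactly; broadband sensor noise is strongly attenuated while PPG
systolic peaks survive. One consequence worth knowing: at 256 Hz this
window also attenuates in-band EEG power above ~8 Hz appreciably (alpha
power retains roughly a third of its raw value). Because the attenuation
is identical for both channels of a symmetric pair, asymmetry ratios
remain monotone in the generative gain — the measured RASM for a true
right/left ratio of 1.8 comes out near 1.65 — and the raw-signal spectral
fidelity of the generator is tested separately without smoothing.

Band powers use a Welch averaged periodogram: 2 s Hann-windowed,
mean-detrended segments with 50% overlap, integrated over half-open bands
delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–45 Hz (the
conventional ranges; half-open intervals prevent shared-edge
double-counting). A unit sinusoid reproduces its 0.5 total power in-band
to ~2% (Parseval), and white-noise band powers are proportional to
bandwidth. The analysis epoch is the whole clip.

## Features (36 per session)

* **EEG (30):** for each pair (AF7, AF8) frontal and (TP9, TP10) temporal
  — 10–20 convention, odd = left — and each band *b*: rational asymmetry
  `RASM_b = PR_b / PL_b`, differential asymmetry `DASM_b = PR_b - PL_b`
  (whole-epoch scalar band powers), and `C_b`, the Pearson correlation of
  the left and right sliding-window band-power series (2 s window, 1 s
  hop; windows are the index set over which the correlation sum runs).
  Order is pair-major, band-minor, feature-minor with frozen names like
  `frontal_alpha_rasm`.
* **GSR (4):** population variance V, Shannon entropy E of the 16-bin
  equal-width value histogram (natural log; the estimator for the value
  distribution had to be chosen, and an equal-width histogram over the
  data range is the simplest defensible one — it makes E invariant to
  affine rescaling), kurtosis K and skewness S. K and S use the
  conventional dimensionless moment ratios `m4/m2^2` and `m3/m2^(3/2)`;
  a `literal_kurtosis` flag exposes the raw `m4/m2` ratio for
  compatibility with sources that print that form.
* **PPG (2):** systolic peaks are detected on the smoothed,
  median-detrended waveform as local maxima with topographic prominence
  ≥ 0.5 SD and ≥ 0.33 s separation (a 180 bpm refractory bound); "R-peak"
  terminology from ECG maps to systolic pulse peaks here, since PPG has
  no QRS complex. HR is `(n_peaks - 1) / span * 60` (bpm); HRV is
  summarized as the *mean* inter-beat interval in ms (the package also
  attaches SDNN as an attribute, outside the 36-feature vector).

## Fusion and classification

Modality-level fusion concatenates feature blocks (canonical order EEG,
GSR, PPG) before a single classifier; all 7 nonempty modality subsets are
evaluated. The classifier is KNN with Euclidean distance on z-scored
features — raw features mix uV^2, ratios, uS^2 and ms, so unscaled
distance would be dominated by whichever block has the largest numbers.
Cross-validation is 10-fold, stratified by label with a balanced
rotating-pointer assignment (fold sizes 8–9 for n = 84, per-class counts
within one), seeded. Normalization parameters are fit on each training
fold only and applied to the held-out fold — the suite verifies the
training-only path by recomputing a fold independently. Class
probabilities are neighbour vote fractions; vote ties go to the class of
the single nearest neighbour among the tied classes (deterministic).
`k = 3` is the default — a small-sample default; no value was prescribed
for this design — and `analysis/03_classify.R` reports sensitivity over
k ∈ {1, 3, 5, 7}.

## Evaluation

From a confusion matrix (rows actual, columns predicted): accuracy
`100 * trace / n`; Cohen's kappa `(p_o - p_e) / (1 - p_e)` with
`p_e = sum_i row_i col_i / n^2` (symmetric in rows/columns, hence
transpose-invariant); per-class sensitivity `TP/row`, specificity
`TN/(TN+FP)`; precision, recall, F with row-total-weighted averages.

From per-instance probability vectors: MAE, RMSE, RAE and RRSE in the
nominal-class probability-vs-indicator convention, with per-instance
baselines equal to the class priors of that instance's training folds; a
baseline that predicts the priors scores RAE = RRSE = 100% by
construction.

The bundled benchmark confusion matrices (`reference_confusion_matrices()`)
are stored exactly as published. The EEG matrix is row-oriented (row sums
equal the class counts 9/22/40/13); the GSR, PPG and fused matrices are
column-oriented. Accuracy and kappa are orientation-invariant, so all four
are usable for those metrics; per-class rate checks are anchored to the
EEG matrix only. Two published specificities for that matrix (relaxed
94.0%, happy 80.0%) differ by ~0.5 points from direct recomputation
(93.3%, 79.5%) and are not used as checks.

## Statistical checks on the synthetic study

With the default (deliberately strong-effect) generator, fused 10-fold
accuracy is far above the 40/84 ≈ 47.6% majority baseline (binomial
p < 0.01). Under label permutation the theoretical chance rate for a
prior-tracking classifier is `sum_c p_c^2 ≈ 33.1%`, *below* the majority
rate — so the permutation check asserts the two things that are actually
true under the null: no significant accuracy above the majority baseline,
and consistency with the `sum p_c^2` chance rate.

## Problem sizes and runtime

The test suite generates the full 84-session study once (~30 s) and
memoizes it; cheap structural tests use 4-session, 20 s-clip configs. The
whole suite runs in well under a minute; the acceptance script regenerates
the study from scratch in under a minute. These sizes are the package's
chosen defaults for a complete, reproducible demonstration of the design.

## Known limitations

* Synthetic EEG is stationary band noise: no artifacts, no nonstationary
  rhythms, no volume conduction. Real-data performance claims cannot be
  made from it.
* The GSR feature set (global moments + entropy) is weakly informative
  about SCR rate at these durations; on the synthetic study GSR-only
  classification sits near chance, and arousal information enters mainly
  through PPG.
* The Savitzky–Golay default trades in-band EEG power for noise rejection
  (see Pre-processing); the window parameters are exposed if a different
  trade-off is wanted.
* HRV-as-mean-IBI is (up to peak-detection error) a monotone transform of
  HR; it adds robustness, not independent information.
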