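# Shared fixtures, built in code. The full default study (84 sessions,
# 84 x 36 features) takes ~30 s, so it is generated once per test run and
# memoized for every test that needs the study-scale conditions.

.fixture_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.fixture_cache$study)) {
    cfg <- synth_config(master_seed = 20260921)
    ds <- generate_dataset(cfg)
    features <- build_feature_matrix(ds$recordings)
    labels <- label_emotion(ds$manifest$valence, ds$manifest$arousal)
    .fixture_cache$study <- list(config = cfg, dataset = ds,
                                 features = features, labels = labels)
  }
  .fixture_cache$study
}

# A cheap 4-session config (one participant, 20 s clips, one session per
# emotion) for tests that only need a structurally valid session.
small_config <- function(noise_sd = list(eeg = 2, gsr = 0.01, ppg = 0.05),
                         ...) {
  synth_config(n_participants = 1, clip_durations_s = rep(20, 4),
               class_counts = c(relaxed = 1, sad = 1, happy = 1, angry = 1),
               noise_sd = noise_sd, master_seed = 99, ...)
}

# One near-noiseless session under a custom emotion parameter row.
quiet_session <- function(emotion = "happy", params = NULL,
                          duration = 58, seed = 4242) {
  ep <- default_emotion_params()
  if (!is.null(params))
    for (nm in names(params)) ep[ep$emotion == emotion, nm] <- params[[nm]]
  cfg <- synth_config(n_participants = 1, clip_durations_s = rep(duration, 4),
                      class_counts = c(relaxed = 1, sad = 1,
                                       happy = 1, angry = 1),
                      emotion_params = ep,
                      noise_sd = list(eeg = 1e-3, gsr = 1e-4, ppg = 1e-3))
  generate_session(cfg, 1, 1, emotion, seed = seed)
}

# Build a cv_result-shaped data frame by hand (for evaluation oracles).
fake_cv <- function(truth, pred = truth, prob, fold = 1L) {
  stopifnot(ncol(prob) == 4)
  res <- data.frame(session = seq_along(truth), fold = fold,
                    truth = factor(truth, levels = emotion_levels()),
                    pred = factor(pred, levels = emotion_levels()))
  colnames(prob) <- paste0("prob_", emotion_levels())
  res <- cbind(res, prob)
  class(res) <- c("cv_result", "data.frame")
  res
}
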