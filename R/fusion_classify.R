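#' Canonical names of the 36 fused features
#'
#' 30 EEG features ([eeg_feature_names()]) followed by the 4 GSR features
#' (`gsr_variance`, `gsr_entropy`, `gsr_kurtosis`, `gsr_skewness`) and the 2
#' PPG features (`ppg_hr`, `ppg_hrv`).
#'
#' @return Character vector of length 36.
#' @export
feature_names <- function() {
  c(eeg_feature_names(),
    "gsr_variance", "gsr_entropy", "gsr_kurtosis", "gsr_skewness",
    "ppg_hr", "ppg_hrv")
}

# Which canonical columns belong to each modality.
modality_columns <- function(modalities) {
  cols <- character(0)
  if ("eeg" %in% modalities) cols <- c(cols, eeg_feature_names())
  if ("gsr" %in% modalities)
    cols <- c(cols, "gsr_variance", "gsr_entropy", "gsr_kurtosis",
              "gsr_skewness")
  if ("ppg" %in% modalities) cols <- c(cols, "ppg_hr", "ppg_hrv")
  cols
}

#' Extract the full 36-value feature vector of one session
#'
#' Runs the three modality extractors on a (raw) session recording: EEG
#' asymmetry/correlation features on the smoothed EEG channels, the four
#' statistical features on the smoothed GSR channel, and heart rate plus
#' mean inter-beat interval from detected PPG pulse peaks.
#'
#' @param recording A `session_recording`.
#' @param savgol_window,savgol_order Smoothing parameters shared by all
#'   modalities.
#' @return Named numeric vector of length 36 in canonical order.
#' @export
extract_features <- function(recording, savgol_window = 31,
                             savgol_order = 3) {
  eeg <- extract_eeg_features(recording, savgol_window, savgol_order)
  gsr_sm <- savgol_smooth(recording$signals$GSR, savgol_window, savgol_order)
  g <- gsr_features(gsr_sm)
  peaks <- detect_pulse_peaks(recording$signals$PPG, recording$fs)
  p <- c(heart_rate(peaks), as.numeric(hrv(peaks)))
  out <- c(eeg, g, p)
  names(out) <- feature_names()
  out
}

#' Build the session x feature matrix for a dataset
#'
#' @param recordings List of `session_recording`s.
#' @param ... Passed to [extract_features()].
#' @return Numeric matrix, one row per session, 36 canonical columns; row
#'   names `participant.clip`.
#' @export
build_feature_matrix <- function(recordings, ...) {
  rows <- lapply(recordings, extract_features, ...)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(recordings, function(r)
    paste(r$participant_id, r$clip_id, sep = "."), character(1))
  m
}

#' Modality-level fusion: select feature columns
#'
#' Modality-level fusion concatenates the per-modality feature blocks into
#' one matrix before a single classifier sees them (as opposed to
#' decision-level fusion, which combines per-modality classifiers).
#' All 7 nonempty subsets of \{eeg, gsr, ppg\} are supported; columns keep
#' the canonical modality order EEG, GSR, PPG.
#'
#' @param features Full 36-column feature matrix ([build_feature_matrix()]).
#' @param modalities Character subset of `c("eeg", "gsr", "ppg")`.
#' @return Column subset of `features`.
#' @export
fuse <- function(features, modalities = c("eeg", "gsr", "ppg")) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  cols <- modality_columns(modalities)
  missing <- setdiff(cols, colnames(features))
  if (length(missing))
    stop("feature matrix is missing columns: ",
         paste(missing, collapse = ", "))
  features[, cols, drop = FALSE]
}

#' k-nearest-neighbour prediction with vote-fraction probabilities
#'
#' Euclidean-distance KNN. For each query row the class-probability vector
#' is the fraction of the k nearest training rows voting for each class (in
#' canonical class order); the predicted label is the modal vote, with ties
#' between top classes broken in favour of the class of the single nearest
#' neighbour among the tied classes. Features are used as given: callers are
#' expected to z-score them (see [cross_validate()], which fits the scaling
#' on each training fold only).
#'
#' @param train Numeric training matrix (rows = instances).
#' @param labels Factor of training labels with levels `emotion_levels()`.
#' @param query Numeric matrix (or vector) of query rows, same columns.
#' @param k Number of neighbours, `1 <= k < nrow(train)`.
#' @return List with `label` (factor, one per query row) and `prob`
#'   (matrix, rows = queries, 4 canonical class columns, rows sum to 1).
#' @export
knn_predict <- function(train, labels, query, k = 3) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  if (k < 1 || k > nrow(train)) stop("k must satisfy 1 <= k <= nrow(train)")
  labels <- factor(labels, levels = emotion_levels())
  nq <- nrow(query)
  prob <- matrix(0, nq, 4, dimnames = list(NULL, emotion_levels()))
  pred <- character(nq)
  for (q in seq_len(nq)) {
    d2 <- colSums((t(train) - query[q, ])^2)
    nn <- order(d2)[seq_len(k)]
    votes <- table(labels[nn]) / k
    prob[q, ] <- as.numeric(votes)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) {
      pred[q] <- top
    } else {
      # tie: nearest single neighbour among the tied classes wins
      nearest_tied <- nn[which(as.character(labels[nn]) %in% top)[1]]
      pred[q] <- as.character(labels[nearest_tied])
    }
  }
  list(label = factor(pred, levels = emotion_levels()), prob = prob)
}

# Balanced stratified fold assignment: classes are shuffled internally and
# dealt onto folds with one rotating pointer, so per-class counts per fold
# differ by at most 1 and overall fold sizes differ by at most 1.
stratified_folds <- function(labels, n_folds) {
  n <- length(labels)
  fold <- integer(n)
  ptr <- 0L
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    for (i in idx) {
      fold[i] <- ptr %% n_folds + 1L
      ptr <- ptr + 1L
    }
  }
  fold
}

#' Stratified k-fold cross-validated KNN
#'
#' Splits sessions into `n_folds` label-stratified folds (seeded), then for
#' each fold fits z-score normalization parameters on the training portion
#' only, scales both portions with them, and predicts the held-out fold
#' with [knn_predict()]. Every session is predicted exactly once by a model
#' that never saw it; normalization statistics never leak from test folds.
#'
#' @param features Numeric feature matrix (rows = sessions).
#' @param labels Factor of true labels, levels `emotion_levels()`.
#' @param k Neighbour count (default 3).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param normalize Z-score features per training fold (default TRUE).
#' @return A `cv_result` data frame: one row per session with `session`,
#'   `fold`, `truth`, `pred` and the four class-probability columns
#'   `prob_relaxed`, `prob_sad`, `prob_happy`, `prob_angry`. The
#'   configuration is attached as attribute `"config"`.
#' @export
cross_validate <- function(features, labels, k = 3, n_folds = 10,
                           seed = 1, normalize = TRUE) {
  labels <- factor(labels, levels = emotion_levels())
  n <- nrow(features)
  if (n < n_folds) stop("need at least n_folds sessions")
  if (any(table(labels) == 0))
    warning("some classes have no instances")
  fold <- with_local_seed(seed, stratified_folds(labels, n_folds))
  pred <- factor(rep(NA_character_, n), levels = emotion_levels())
  prob <- matrix(NA_real_, n, 4, dimnames = list(NULL, emotion_levels()))
  for (f in sort(unique(fold))) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (any(table(labels[tr]) == 0))
      warning("class absent from training fold ", f, "; proceeding")
    xtr <- features[tr, , drop = FALSE]
    xte <- features[te, , drop = FALSE]
    if (normalize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    }
    out <- knn_predict(xtr, labels[tr], xte, k = k)
    pred[te] <- out$label
    prob[te, ] <- out$prob
  }
  res <- data.frame(session = seq_len(n), fold = fold,
                    truth = labels, pred = pred)
  colnames(prob) <- paste0("prob_", emotion_levels())
  res <- cbind(res, prob)
  attr(res, "config") <- list(k = k, n_folds = n_folds, seed = seed,
                              normalize = normalize)
  class(res) <- c("cv_result", "data.frame")
  res
}
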