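#' Write a session recording to CSV
#'
#' One row per sample, columns `t_s, TP9, AF7, AF8, TP10, GSR, PPG`.
#'
#' @param recording A `session_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(recording, path) {
  utils::write.csv(recording$signals, path, row.names = FALSE)
  invisible(path)
}

#' Read a session recording from CSV
#'
#' Expects the schema written by [write_session_csv()]. The sampling rate is
#' inferred from the median time step and the time column must be uniform
#' to within 1% of it; a declared `fs` (if given) must also agree within 1%.
#'
#' @param path CSV file path.
#' @param participant,clip Identifiers to attach (defaults NA).
#' @param fs Optional declared sampling rate, Hz.
#' @return A `session_recording`.
#' @export
read_session_csv <- function(path, participant = NA, clip = NA, fs = NULL) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("empty session file: ", path)
  required <- c("t_s", "TP9", "AF7", "AF8", "TP10", "GSR", "PPG")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("session file missing column(s): ", paste(missing, collapse = ", "))
  dt <- diff(df$t_s)
  if (any(dt <= 0)) stop("time column must be strictly increasing")
  step <- stats::median(dt)
  if (any(abs(dt - step) > 0.01 * step))
    stop("non-uniform sampling beyond 1% tolerance")
  fs_inferred <- 1 / step
  if (!is.null(fs) && abs(fs_inferred - fs) > 0.01 * fs)
    stop(sprintf("inferred fs %.2f Hz differs from declared %g Hz",
                 fs_inferred, fs))
  structure(list(participant_id = participant, clip_id = clip,
                 fs = if (is.null(fs)) fs_inferred else fs,
                 n_samples = nrow(df), signals = df[required]),
            class = "session_recording")
}

#' Reference confusion matrices for the four-emotion benchmark
#'
#' The published benchmark confusion matrices for this emotion-recognition
#' task (84 sessions; 9 relaxed / 22 sad / 40 happy / 13 angry) under each
#' single modality and under modality-level fusion. They are bundled so the
#' full evaluation surface can be verified against known results without
#' any recordings. Matrices are stored exactly as published: in the `eeg`
#' matrix rows are actual classes (row sums match the class counts); in the
#' `gsr`, `ppg` and `fused` matrices the actual classes run along the
#' columns instead. Accuracy and Cohen's kappa are invariant to that
#' orientation; per-class rate checks should use the `eeg` matrix.
#'
#' @return Named list of four 4x4 integer matrices (`eeg`, `gsr`, `ppg`,
#'   `fused`), dimnames in canonical class order.
#' @export
reference_confusion_matrices <- function() {
  path <- system.file("extdata", "reference_confusion_matrices.csv",
                      package = "affectfuse", mustWork = TRUE)
  df <- utils::read.csv(path)
  out <- lapply(split(df, factor(df$modality,
                                 c("eeg", "gsr", "ppg", "fused"))),
                function(d) {
    m <- as.matrix(d[match(emotion_levels(), d$row), emotion_levels()])
    dimnames(m) <- list(emotion_levels(), emotion_levels())
    structure(m, class = "confusion_matrix")
  })
  out
}
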