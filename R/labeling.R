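#' Emotion classes in canonical order
#'
#' The four Russell-quadrant emotions handled by this package, in the fixed
#' canonical order used for every labels factor, probability vector and
#' confusion matrix: relaxed, sad, happy, angry.
#'
#' @return Character vector of length 4.
#' @export
emotion_levels <- function() c("relaxed", "sad", "happy", "angry")

#' Map SAM valence/arousal ratings to Russell-quadrant emotion labels
#'
#' Self-Assessment Manikin (SAM) ratings place a session in valence-arousal
#' space on 9-point scales. The Russell circumplex partitions that plane at
#' the scale midpoint into four quadrants: high valence & high arousal is
#' happy, low valence & high arousal is angry, low valence & low arousal is
#' sad, and high valence & low arousal is relaxed. Scores equal to the
#' midpoint are assigned to the low side; the default generator never emits
#' midpoint scores, so this boundary policy is a documented tie-break rather
#' than a modelling choice.
#'
#' @param valence Integer vector, valence ratings in 1..9.
#' @param arousal Integer vector, arousal ratings in 1..9 (same length).
#' @param midpoint Scale midpoint separating "low" from "high" (default 5).
#' @return Factor with levels `emotion_levels()`.
#' @examples
#' label_emotion(7, 7)            # happy
#' label_emotion(c(3, 3, 7), c(7, 3, 3))  # angry, sad, relaxed
#' @export
label_emotion <- function(valence, arousal, midpoint = 5) {
  if (length(valence) != length(arousal))
    stop("valence and arousal must have the same length")
  if (any(valence < 1 | valence > 9 | arousal < 1 | arousal > 9))
    stop("SAM ratings must lie in [1, 9]")
  hv <- valence > midpoint
  ha <- arousal > midpoint
  lab <- ifelse(hv & ha, "happy",
         ifelse(!hv & ha, "angry",
         ifelse(!hv & !ha, "sad", "relaxed")))
  factor(lab, levels = emotion_levels())
}

#' Label a set of sessions and summarize class counts
#'
#' @param ratings Data frame with columns `valence` and `arousal`.
#' @param midpoint Scale midpoint, see [label_emotion()].
#' @return List with `labels` (factor) and `counts` (named integer vector in
#'   canonical class order; empty classes count 0).
#' @export
label_dataset <- function(ratings, midpoint = 5) {
  stopifnot(is.data.frame(ratings), nrow(ratings) > 0,
            all(c("valence", "arousal") %in% names(ratings)))
  labels <- label_emotion(ratings$valence, ratings$arousal, midpoint)
  list(labels = labels, counts = table(labels))
}
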