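#' Confusion matrix from cross-validation results
#'
#' Rows are actual classes, columns predicted classes, both in the fixed
#' canonical order relaxed, sad, happy, angry.
#'
#' @param truth Factor of true labels, or a `cv_result` (then `pred` is
#'   taken from it).
#' @param pred Factor of predicted labels (ignored when `truth` is a
#'   `cv_result`).
#' @return 4x4 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, pred = NULL) {
  if (inherits(truth, "cv_result")) {
    pred <- truth$pred
    truth <- truth$truth
  }
  truth <- factor(truth, levels = emotion_levels())
  pred <- factor(pred, levels = emotion_levels())
  m <- unclass(table(actual = truth, predicted = pred))
  structure(m, class = "confusion_matrix")
}

as_confusion <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (!all(dim(cm) == c(4, 4)) || any(cm < 0) || sum(cm) == 0)
    stop("expected a 4x4 nonnegative count matrix with positive total")
  cm
}

#' Overall accuracy (percent)
#'
#' `100 * trace / n`: the percentage of instances on the diagonal.
#'
#' @param cm 4x4 confusion matrix (rows actual, columns predicted).
#' @return Accuracy in percent.
#' @export
accuracy <- function(cm) {
  cm <- as_confusion(cm)
  100 * sum(diag(cm)) / sum(cm)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/n` and expected agreement
#' `p_e = sum_i row_i * col_i / n^2`. Because `p_e` is symmetric in rows
#' and columns, kappa is invariant under matrix transposition.
#'
#' @param cm 4x4 confusion matrix.
#' @return Kappa in (-1, 1).
#' @export
cohen_kappa <- function(cm) {
  cm <- as_confusion(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) stop("expected agreement is 1; kappa undefined")
  (po - pe) / (1 - pe)
}

#' Per-class sensitivity and specificity
#'
#' Sensitivity (true-positive rate) of class c is `cm[c,c] / row_c`;
#' specificity is `TN_c / (TN_c + FP_c)` with `FP_c = col_c - cm[c,c]` and
#' `TN_c = n - row_c - FP_c`. An empty class row yields `NaN` sensitivity.
#'
#' @param cm 4x4 confusion matrix (rows actual).
#' @return Data frame with `class`, `sensitivity`, `specificity`
#'   (proportions in \[0, 1\]).
#' @export
per_class_rates <- function(cm) {
  cm <- as_confusion(cm)
  n <- sum(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  tp <- diag(cm)
  fp <- cs - tp
  tn <- n - rs - fp
  data.frame(class = emotion_levels(),
             sensitivity = ifelse(rs > 0, tp / rs, NaN),
             specificity = tn / (tn + fp))
}

#' Per-class and weighted precision, recall and F-score
#'
#' `precision_c = cm[c,c] / col_c`, `recall_c = cm[c,c] / row_c`,
#' `F_c = 2PR/(P+R)`; classes with a zero denominator get 0 with a warning.
#' Weighted averages use actual class frequencies (row totals) as weights.
#'
#' @param cm 4x4 confusion matrix (rows actual).
#' @return List with `per_class` (data frame) and `weighted` (named vector).
#' @export
precision_recall_f <- function(cm) {
  cm <- as_confusion(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  tp <- diag(cm)
  zero <- cs == 0 | rs == 0
  if (any(zero))
    warning("zero-denominator class(es): ",
            paste(emotion_levels()[zero], collapse = ", "),
            "; precision/recall reported as 0")
  precision <- ifelse(cs > 0, tp / cs, 0)
  recall <- ifelse(rs > 0, tp / rs, 0)
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  w <- rs / sum(rs)
  list(
    per_class = data.frame(class = emotion_levels(), precision = precision,
                           recall = recall, f_score = f),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f_score = sum(w * f))
  )
}

#' Nominal-class probability error statistics
#'
#' Error rates of the per-class probability outputs against the 0/1 truth
#' indicators, in the convention standard for nominal-class evaluation:
#' with `p_ij` the predicted probability of class j for instance i, `y_ij`
#' the truth indicator and `q_ij` the baseline (class prior of the
#' instance's training fold),
#' `MAE = mean |p - y|`, `RMSE = sqrt(mean (p - y)^2)`,
#' `RAE = 100 * sum|p - y| / sum|q - y|` and
#' `RRSE = 100 * sqrt(sum (p - y)^2 / sum (q - y)^2)`.
#' A baseline that always predicts the priors scores RAE = RRSE = 100%.
#'
#' @param cv A `cv_result` (needs `fold`, `truth` and the `prob_*` columns).
#' @param priors Optional 4-column matrix of baseline probabilities, one
#'   row per instance; by default the class frequencies of each instance's
#'   training folds.
#' @return Named vector `c(mae, rmse, rae, rrse)` (rae/rrse in percent).
#' @export
nominal_error_stats <- function(cv, priors = NULL) {
  stopifnot(inherits(cv, "cv_result") || is.data.frame(cv))
  pcols <- paste0("prob_", emotion_levels())
  p <- as.matrix(cv[, pcols])
  y <- outer(as.character(cv$truth), emotion_levels(), "==") * 1
  if (is.null(priors)) {
    priors <- t(vapply(cv$fold, function(f) {
      tr <- cv$truth[cv$fold != f]
      as.numeric(table(tr) / length(tr))
    }, numeric(4)))
  }
  if (is.null(dim(priors)) || !all(dim(priors) == dim(p)))
    stop("priors must be an n x 4 matrix")
  mae <- mean(abs(p - y))
  rmse <- sqrt(mean((p - y)^2))
  rae <- 100 * sum(abs(p - y)) / sum(abs(priors - y))
  rrse <- 100 * sqrt(sum((p - y)^2) / sum((priors - y)^2))
  c(mae = mae, rmse = rmse, rae = rae, rrse = rrse)
}

#' Full metric report for one cross-validation run
#'
#' @param cv A `cv_result`.
#' @return List with `confusion`, `accuracy` (%), `kappa`, `rates`
#'   (sensitivity/specificity), `prf` (precision/recall/F) and `errors`
#'   (MAE/RMSE/RAE/RRSE).
#' @export
metric_report <- function(cv) {
  cm <- confusion(cv)
  list(confusion = cm, accuracy = accuracy(cm), kappa = cohen_kappa(cm),
       rates = per_class_rates(cm), prf = precision_recall_f(cm),
       errors = nominal_error_stats(cv))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = actual, columns = predicted\n")
  print(unclass(x))
  invisible(x)
}
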