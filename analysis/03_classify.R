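#!/usr/bin/env Rscript
# Classify the four emotions with KNN under 10-fold stratified
# cross-validation, for every nonempty modality combination (modality-level
# fusion), plus a sensitivity sweep over k. Reads the feature matrix
# written by 02_extract_features.R.

library(affectfuse)

seed <- 20260921
out <- "results"
fm_path <- file.path(out, "feature_matrix.csv")
if (!file.exists(fm_path))
  stop("run analysis/02_extract_features.R first")

fm <- read.csv(fm_path, check.names = FALSE)
features <- as.matrix(fm[, -1])
rownames(features) <- fm$session
labels <- factor(read.csv(file.path(out, "labels.csv"))$label,
                 levels = emotion_levels())

summary_rows <- list()
for (nm in names(modality_masks())) {
  cv <- cross_validate(fuse(features, modality_masks()[[nm]]), labels,
                       k = 3, n_folds = 10, seed = seed)
  rep <- metric_report(cv)
  summary_rows[[nm]] <- data.frame(
    modality = nm, accuracy_pct = rep$accuracy, kappa = rep$kappa,
    mae = rep$errors[["mae"]], rmse = rep$errors[["rmse"]],
    rae_pct = rep$errors[["rae"]], rrse_pct = rep$errors[["rrse"]])
  write.csv(as.data.frame(unclass(rep$confusion)),
            file.path(out, paste0("confusion_", nm, ".csv")))
}
tab <- do.call(rbind, summary_rows)
print(tab, digits = 3, row.names = FALSE)
write.csv(tab, file.path(out, "cv_summary.csv"), row.names = FALSE)

cat("\nSensitivity to k (fused features):\n")
k_rows <- lapply(c(1, 3, 5, 7), function(k) {
  cv <- cross_validate(fuse(features), labels, k = k, n_folds = 10,
                       seed = seed)
  data.frame(k = k, accuracy_pct = accuracy(confusion(cv)))
})
k_tab <- do.call(rbind, k_rows)
print(k_tab, row.names = FALSE)
write.csv(k_tab, file.path(out, "k_sensitivity.csv"), row.names = FALSE)
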