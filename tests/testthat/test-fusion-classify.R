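test_that("fusion selects canonical column blocks for all 7 masks", {
  study <- default_study()
  fm <- study$features
  expect_equal(dim(fuse(fm)), c(84, 36))
  expect_equal(dim(fuse(fm, "ppg")), c(84, 2))
  expect_equal(dim(fuse(fm, c("eeg", "gsr"))), c(84, 34))
  widths <- vapply(modality_masks(), function(m) ncol(fuse(fm, m)),
                   numeric(1))
  expect_equal(unname(widths), c(30, 4, 2, 34, 32, 6, 36))
  # canonical modality order regardless of mask order
  expect_equal(colnames(fuse(fm, c("ppg", "eeg")))[1], "frontal_delta_rasm")
  expect_error(fuse(fm[, 1:10], "gsr"), "missing columns")
})

test_that("full per-session extraction yields 36 named features", {
  s <- generate_session(small_config(), 1, 1, "angry")$recording
  f <- extract_features(s)
  expect_length(f, 36)
  expect_equal(names(f), feature_names())
  expect_false(anyNA(f))
})

test_that("KNN votes, probabilities and tie-breaks follow the contract", {
  train <- matrix(c(0, 0, 0.1, 0, 5, 5, 5.1, 5, 10, 10), ncol = 2,
                  byrow = TRUE)
  labs <- factor(c("happy", "happy", "sad", "sad", "relaxed"),
                 levels = emotion_levels())
  # query equal to a training point, k = 1
  out <- knn_predict(train, labs, train[3, ], k = 1)
  expect_equal(as.character(out$label), "sad")
  expect_equal(unname(out$prob[1, ]), c(0, 1, 0, 0))
  # k = 3 vote fractions in canonical order
  out3 <- knn_predict(train, labs, c(0.05, 0), k = 3)
  expect_equal(as.character(out3$label), "happy")
  expect_equal(unname(out3$prob[1, ]), c(0, 1 / 3, 2 / 3, 0))
  # 2-2 tie at k = 4: the nearest single neighbour's class wins
  tie <- knn_predict(train[1:4, ], labs[1:4], c(0.1, 0.01), k = 4)
  expect_equal(unname(tie$prob[1, ]), c(0, 0.5, 0.5, 0))
  expect_equal(as.character(tie$label), "happy")
  expect_error(knn_predict(train, labs, c(0, 0), k = 9), "k must")
})

test_that("KNN separates well-separated clusters and matches class::knn", {
  withr::with_seed(31, {
    n <- 40
    x <- rbind(matrix(rnorm(2 * n), ncol = 2),
               matrix(rnorm(2 * n, mean = 10), ncol = 2))
    y <- factor(rep(c("happy", "sad"), each = n), levels = emotion_levels())
    q <- rbind(matrix(rnorm(2 * 10), ncol = 2),
               matrix(rnorm(2 * 10, mean = 10), ncol = 2))
    truth <- rep(c("happy", "sad"), each = 10)
    out <- knn_predict(x, y, q, k = 3)
    expect_equal(as.character(out$label), truth)
    # brute-force single-nearest-neighbour scan agrees at k = 1
    nn1 <- apply(q, 1, function(r)
      as.character(y[which.min(colSums((t(x) - r)^2))]))
    out1 <- knn_predict(x, y, q, k = 1)
    expect_equal(as.character(out1$label), nn1)
    skip_if_not_installed("class")
    ref <- as.character(class::knn(x, q, y, k = 3))
    expect_equal(as.character(out$label), ref)
  })
})

test_that("cross-validation partitions sessions into balanced stratified folds", {
  study <- default_study()
  cv <- cross_validate(fuse(study$features, "ppg"), study$labels,
                       k = 3, n_folds = 10, seed = 5)
  expect_s3_class(cv, "cv_result")
  expect_equal(sort(unique(cv$fold)), 1:10)
  expect_true(all(table(cv$fold) %in% c(8, 9)))
  expect_equal(cv$session, 1:84)          # every session predicted once
  expect_false(anyNA(cv$pred))
  probs <- as.matrix(cv[, paste0("prob_", emotion_levels())])
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, 84))
  # per-fold class composition is balanced to within one instance
  per_fold <- table(cv$fold, cv$truth)
  expect_true(all(apply(per_fold, 2, function(col) diff(range(col)) <= 1)))
})

test_that("cross-validation is deterministic in its seed", {
  study <- default_study()
  x <- fuse(study$features, c("gsr", "ppg"))
  cv1 <- cross_validate(x, study$labels, seed = 9)
  cv2 <- cross_validate(x, study$labels, seed = 9)
  expect_identical(cv1, cv2)
  cv3 <- cross_validate(x, study$labels, seed = 10)
  expect_false(identical(cv1$fold, cv3$fold))
})

test_that("normalization statistics come from training folds only", {
  study <- default_study()
  x <- fuse(study$features, c("eeg", "ppg"))
  cv <- cross_validate(x, study$labels, k = 3, n_folds = 10, seed = 13)
  # independently recompute one fold: z-score with train-only statistics,
  # then a brute-force neighbour vote
  f <- 4
  te <- which(cv$fold == f); tr <- which(cv$fold != f)
  mu <- colMeans(x[tr, ]); sdv <- apply(x[tr, ], 2, sd); sdv[sdv == 0] <- 1
  ztr <- sweep(sweep(x[tr, ], 2, mu), 2, sdv, "/")
  zte <- sweep(sweep(x[te, ], 2, mu), 2, sdv, "/")
  redo <- knn_predict(ztr, study$labels[tr], zte, k = 3)
  expect_equal(as.character(cv$pred[te]), as.character(redo$label))
  # a leaky path (scaling fit on the pooled data) gives different test-fold
  # coordinates, so agreement above is evidence the training-only path is used
  mu_all <- colMeans(x); sd_all <- apply(x, 2, sd)
  zte_leaky <- sweep(sweep(x[te, ], 2, mu_all), 2, sd_all, "/")
  expect_gt(max(abs(zte_leaky - zte)), 0.01)
})
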