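test_that("confusion tallies predictions with canonical ordering", {
  truth <- c("happy", "happy", "sad", "angry", "relaxed", "happy")
  pred <- c("happy", "sad", "sad", "happy", "relaxed", "happy")
  cm <- confusion(factor(truth, levels = emotion_levels()),
                  factor(pred, levels = emotion_levels()))
  manual <- matrix(0, 4, 4, dimnames = list(emotion_levels(),
                                            emotion_levels()))
  manual["relaxed", "relaxed"] <- 1
  manual["sad", "sad"] <- 1
  manual["happy", "happy"] <- 2; manual["happy", "sad"] <- 1
  manual["angry", "happy"] <- 1
  expect_equal(unclass(cm), manual, ignore_attr = TRUE)
  expect_equal(unname(rowSums(cm)), c(1, 1, 3, 1))  # conservation
  # all-correct input gives a diagonal matrix
  cmd <- confusion(factor(truth, levels = emotion_levels()),
                   factor(truth, levels = emotion_levels()))
  expect_equal(sum(cmd) - sum(diag(unclass(cmd))), 0)
})

test_that("accuracy and kappa reach their ideal values on perfect matrices", {
  perfect <- diag(c(9, 22, 40, 13))
  expect_equal(accuracy(perfect), 100)
  expect_equal(cohen_kappa(perfect), 1)
})

test_that("kappa is invariant to transposition and class permutation", {
  m <- matrix(c(6, 1, 2, 0, 0, 15, 6, 1, 4, 2, 33, 1, 1, 2, 1, 9),
              4, 4, byrow = TRUE)
  expect_equal(cohen_kappa(t(m)), cohen_kappa(m))
  perm <- c(3, 1, 4, 2)
  expect_equal(cohen_kappa(m[perm, perm]), cohen_kappa(m))
  expect_equal(accuracy(m[perm, perm]), accuracy(m))
  r1 <- per_class_rates(m); r2 <- per_class_rates(m[perm, perm])
  expect_equal(r2$sensitivity, r1$sensitivity[perm])
  expect_equal(r2$specificity, r1$specificity[perm])
})

test_that("per-class rates and precision/recall/F behave on perfect input", {
  perfect <- diag(c(9, 22, 40, 13))
  rates <- per_class_rates(perfect)
  expect_equal(rates$sensitivity, rep(1, 4))
  expect_equal(rates$specificity, rep(1, 4))
  prf <- precision_recall_f(perfect)
  expect_equal(prf$per_class$precision, rep(1, 4))
  expect_equal(prf$per_class$f_score, rep(1, 4))
  expect_equal(unname(prf$weighted), rep(1, 3))
  # F equals precision when precision = recall
  m <- matrix(c(3, 1, 0, 0, 1, 3, 0, 0, 0, 0, 4, 0, 0, 0, 0, 4), 4, 4,
              byrow = TRUE)
  prf2 <- precision_recall_f(m)
  expect_equal(prf2$per_class$f_score, prf2$per_class$precision)
  # empty class row yields NaN sensitivity, zero-count column warns
  m0 <- diag(c(0, 22, 40, 13))
  expect_true(is.nan(per_class_rates(m0)$sensitivity[1]))
  expect_warning(prf0 <- precision_recall_f(m0), "zero-denominator")
  expect_equal(prf0$per_class$precision[1], 0)
})

test_that("nominal error statistics match hand-computed oracles", {
  # perfect confident predictions: all four errors are zero
  prob <- diag(4)[c(3, 2, 1, 4), ]
  cvp <- fake_cv(c("happy", "sad", "relaxed", "angry"), prob = prob)
  perfect <- nominal_error_stats(cvp, priors = matrix(0.25, 4, 4))
  expect_equal(unname(perfect), c(0, 0, 0, 0))
  # predicting exactly the priors scores RAE = RRSE = 100%
  cvq <- fake_cv(c("happy", "sad", "relaxed", "angry"),
                 prob = matrix(0.25, 4, 4))
  atprior <- nominal_error_stats(cvq, priors = matrix(0.25, 4, 4))
  expect_equal(unname(atprior["rae"]), 100)
  expect_equal(unname(atprior["rrse"]), 100)
  # three-instance worked example, frozen from direct arithmetic:
  # |p-y| sums 0.5 + 1.0 + 0 over 12 cells -> MAE 0.125;
  # squared sums 0.125 + 0.5 + 0 -> RMSE sqrt(0.625/12);
  # uniform baseline: sum|q-y| = 4.5, sum(q-y)^2 = 2.25
  prob3 <- rbind(c(0.75, 0.25, 0, 0), c(0.5, 0.5, 0, 0), c(0, 0, 1, 0))
  cv3 <- fake_cv(c("relaxed", "sad", "happy"),
                 pred = c("relaxed", "relaxed", "happy"), prob = prob3)
  got <- nominal_error_stats(cv3, priors = matrix(0.25, 3, 4))
  expect_equal(unname(got["mae"]), 0.125)
  expect_equal(unname(got["rmse"]), sqrt(0.625 / 12))
  expect_equal(unname(got["rae"]), 100 * 1.5 / 4.5)
  expect_equal(unname(got["rrse"]), 100 * sqrt(0.625 / 2.25))
  # RMSE bound: 0 <= RMSE <= sqrt(MAE)
  expect_lte(got[["rmse"]], sqrt(got[["mae"]]))
})

test_that("default priors are computed from each instance's training folds", {
  truth <- rep(c("happy", "sad"), each = 4)
  cvf <- fake_cv(truth, prob = matrix(0.25, 8, 4),
                 fold = rep(1:2, times = 4))
  # fold 1 instances: training folds hold 2 happy, 2 sad -> priors 0.5/0.5
  got <- nominal_error_stats(cvf)
  q <- c(0, 0.5, 0.5, 0)
  y_first <- c(0, 0, 1, 0)
  denom_abs <- 8 * sum(abs(q - y_first))
  expect_equal(unname(got["rae"]), 100 * 8 * 1.5 / denom_abs)
})

test_that("metric_report bundles the full evaluation surface", {
  study <- default_study()
  cv <- cross_validate(fuse(study$features, "ppg"), study$labels, seed = 3)
  rep <- metric_report(cv)
  expect_s3_class(rep$confusion, "confusion_matrix")
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 100)
  expect_true(rep$kappa > -1 && rep$kappa < 1)
  expect_named(rep$errors, c("mae", "rmse", "rae", "rrse"))
  expect_equal(sum(rep$confusion), 84)
})
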