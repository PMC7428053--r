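test_that("ROC handles the canonical limiting cases", {
  perfect <- roc_curve(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$operating_point$sensitivity, 1)
  expect_equal(perfect$operating_point$specificity, 1)
  expect_equal(perfect$operating_point$distance, 0)

  flat <- roc_curve(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(flat$auc, 0.5)

  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
  expect_error(roc_curve(1:4, c(0, 1, 0)), "differ")
})

test_that("operating point and AUC match exhaustive oracles", {
  set.seed(30)
  for (rep in 1:12) {
    n <- sample(10:100, 1)
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # force some ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    roc <- roc_curve(scores, labels)
    expect_equal(roc$auc, brute_auc(scores, labels), tolerance = 1e-12)
    oracle <- brute_operating_point(scores, labels)
    expect_equal(roc$operating_point$distance, oracle$distance,
                 tolerance = 1e-12)
    # AUC flips under score negation
    expect_equal(roc_curve(-scores, labels)$auc, 1 - roc$auc,
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- rnorm(80); labels <- rbinom(80, 1, 0.4)
  expect_equal(roc_curve(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("confusion counts and metrics agree with brute-force recounts", {
  cm <- confusion_and_metrics(c(1, 0), c(1, 0))
  expect_equal(cm$accuracy, 100)

  cm <- confusion_and_metrics(rep(c(1, 0, 0, 1), c(8, 2, 9, 1)),
                              rep(c(1, 1, 0, 0), c(8, 2, 9, 1)))
  expect_equal(cm$sensitivity, 80)
  expect_equal(cm$specificity, 90)
  expect_equal(cm$accuracy, 85)
  expect_identical(c(cm$tp, cm$fn, cm$tn, cm$fp), c(8L, 2L, 9L, 1L))

  set.seed(2)
  pred <- rbinom(100, 1, 0.5); truth <- rbinom(100, 1, 0.5)
  cm <- confusion_and_metrics(pred, truth, "core")
  expect_identical(cm$tp, sum(pred & truth))
  expect_identical(cm$tn, sum(!pred & !truth))
  expect_equal(cm$accuracy, 100 * mean(pred == truth))
  expect_equal(cm$sensitivity, 100 * sum(pred & truth) / sum(truth))
  expect_identical(sum(cm$table), 100L)
  expect_error(confusion_and_metrics(1:3, 1:4), "differ")
})

test_that("peak assignment matches within tolerance, nearest-first", {
  a <- assign_peaks(1004, tolerance_cm1 = 8)
  expect_true(a$matched)
  expect_equal(a$distance_cm1, 1)
  expect_identical(a$molecules, "Protein (phenylalanine)")

  a <- assign_peaks(1470, tolerance_cm1 = 15)
  expect_true(a$matched)
  expect_identical(a$molecules, "DNA/RNA (adenine, guanine)")
  # but the default 8 cm^-1 window is too narrow for that offset
  expect_false(assign_peaks(1470, tolerance_cm1 = 8)$matched)

  expect_false(assign_peaks(650, tolerance_cm1 = 8)$matched)
  expect_error(assign_peaks(1000, default_peak_reference()[0, ]), "empty")
})

test_that("shrinking the tolerance never creates matches", {
  set.seed(4)
  wns <- runif(40, 602, 1726)
  wide <- assign_peaks(wns, tolerance_cm1 = 15)
  narrow <- assign_peaks(wns, tolerance_cm1 = 6)
  expect_true(all(wide$matched[narrow$matched]))
  expect_true(all(narrow$distance_cm1[narrow$matched] <= 6))
})

test_that("evaluation reports are internally consistent", {
  ch <- separable_cohort(12, seed = 20)
  fit <- grid_search_train(ch, contrast_spec("benign_vs_cancer"),
                           default_grid(fs_C = 0.2, svm_C = 10, gamma = 1e-2),
                           seed = 1)
  ev <- evaluate_classifier(fit, ch)
  pred <- ev$predictions
  cm <- ev$confusion
  expect_equal(ev$metrics$accuracy,
               100 * mean(pred$predicted == pred$truth))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, nrow(pred))
  expect_equal(ev$metrics$auc, 100 * ev$roc$auc)
  expect_identical(ev$metrics$row_unit, "spectrum")
})
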