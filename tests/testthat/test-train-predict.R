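test_that("grouped stratified folds partition rows and respect patients", {
  ch <- preprocess_cohort(quick_cohort(8, 8, seed = 12), 20)
  dm <- build_design_matrix(ch, contrast_spec("benign_vs_cancer"))
  folds <- make_grouped_folds(dm$group, dm$y, 5, seed = 1)
  expect_setequal(unique(folds), 1:5)
  expect_identical(length(folds), nrow(dm$x))
  # all rows of one patient share a fold
  per_patient <- tapply(folds, dm$group, function(f) length(unique(f)))
  expect_true(all(per_patient == 1))
  # folds are a partition: every row in exactly one fold
  expect_identical(sort(unlist(lapply(1:5, function(f) which(folds == f)))),
                   seq_along(folds))
  expect_error(make_grouped_folds(dm$group[dm$y == 1], dm$y[dm$y == 1], 5),
               "Stratification|both classes")
})

test_that("separable toy data trains to perfect CV accuracy within the grid", {
  ch <- separable_cohort(16, seed = 2)
  fit <- grid_search_train(ch, contrast_spec("benign_vs_cancer"), seed = 1)
  expect_equal(max(fit$grid_results$mean_accuracy), 100)
  expect_true(fit$svm_C >= 0.1 && fit$svm_C <= 1000)
  expect_true(fit$gamma >= 1e-4 && fit$gamma <= 1e-1)
  expect_true(fit$fs_C >= 0.05 && fit$fs_C <= 0.5)

  # predicting the training rows back is perfect
  pred <- predict(fit, ch)
  expect_identical(pred$predicted, pred$truth)
  # and repeated calls give identical scores
  expect_identical(pred$score, predict(fit, ch)$score)
})

test_that("training is deterministic given the seed", {
  ch <- preprocess_cohort(quick_cohort(6, 6, seed = 4), 20)
  grid <- default_grid(fs_C = c(0.1, 0.3), svm_C = c(1, 100),
                       gamma = c(1e-3, 1e-2))
  f1 <- grid_search_train(ch, contrast_spec("benign_vs_cancer"), grid,
                          seed = 7)
  f2 <- grid_search_train(ch, contrast_spec("benign_vs_cancer"), grid,
                          seed = 7)
  expect_identical(glance(f1), glance(f2))
  expect_identical(f1$cv_report$folds, f2$cv_report$folds)
  expect_identical(tidy(f1), tidy(f2))
})

test_that("unselected features never influence decision scores", {
  ch <- preprocess_cohort(quick_cohort(6, 6, seed = 9), 20)
  fit <- grid_search_train(ch, contrast_spec("benign_vs_cancer"),
                           default_grid(fs_C = 0.1, svm_C = c(1, 100),
                                        gamma = 1e-2),
                           seed = 2)
  sel <- fit$selection$selected_indices
  expect_gt(length(sel), 0)
  base_scores <- predict(fit, ch)$score

  perturbed <- ch
  unsel <- setdiff(seq_len(ncol(ch$intensity)), sel)
  set.seed(1)
  perturbed$intensity[, unsel] <- perturbed$intensity[, unsel] +
    matrix(abs(rnorm(nrow(ch) * length(unsel), 0, 50)),
           nrow(ch), length(unsel))
  expect_equal(predict(fit, perturbed)$score, base_scores,
               tolerance = 1e-12)
})

test_that("frozen models ignore test-cohort composition", {
  train <- preprocess_cohort(quick_cohort(6, 6, seed = 14), 20)
  fit <- grid_search_train(train, contrast_spec("benign_vs_cancer"),
                           default_grid(fs_C = 0.1, svm_C = 10, gamma = 1e-2),
                           seed = 3)
  test_big <- preprocess_cohort(quick_cohort(6, 6, seed = 15), 20)
  drop_patient <- utils::tail(unique(test_big$patient_id), 1)
  test_small <- test_big[test_big$patient_id != drop_patient, ]
  p_big <- predict(fit, test_big)
  p_small <- predict(fit, test_small)
  keep <- p_big$patient_id != drop_patient
  expect_identical(p_small$patient_id, p_big$patient_id[keep])
  expect_equal(p_small$score, p_big$score[keep], tolerance = 1e-12)
})

test_that("decision values equal the explicit kernel expansion", {
  ch <- separable_cohort(10, seed = 6)
  dm <- build_design_matrix(ch, contrast_spec("benign_vs_cancer"))
  z <- apply_standardization(dm$x, fit_standardization(dm$x))
  model <- ramanidc:::fit_rbf_svm(z, dm$y, cost = 10, gamma = 0.05)
  scores <- ramanidc:::svm_scores(model, z)

  sv <- model$fit$SV
  manual <- sapply(seq_len(nrow(z)), function(i) {
    k <- exp(-0.05 * colSums((t(sv) - z[i, ])^2))
    sum(model$fit$coefs * k) - model$fit$rho
  })
  expect_equal(scores, model$flip * manual, tolerance = 1e-6)
})

test_that("shuffled labels yield chance-level cross-validation accuracy", {
  set.seed(77)
  n <- 200
  x <- matrix(abs(rnorm(n * 25, 10, 2)), n, 25)
  labels <- sample(rep(c("benign", "cancer"), each = n / 2))
  ch <- matrix_cohort(x, labels)
  fit <- grid_search_train(ch, contrast_spec("benign_vs_cancer"),
                           default_grid(fs_C = 0.2, svm_C = 1, gamma = 1e-2),
                           seed = 5)
  acc <- fit$cv_report$summary$mean[
    fit$cv_report$summary$metric == "accuracy"]
  band <- 100 * 1.96 * sqrt(0.25 / n)
  expect_gt(acc, 50 - band)
  expect_lt(acc, 50 + band)
})

test_that("axis mismatches between model and cohort are refused", {
  ch <- separable_cohort(8, seed = 3)
  fit <- grid_search_train(ch, contrast_spec("benign_vs_cancer"),
                           default_grid(fs_C = 0.2, svm_C = 10, gamma = 1e-2),
                           seed = 1)
  other <- preprocess_cohort(quick_cohort(3, 3, seed = 1), 20)
  expect_error(predict(fit, other), "axis")
})
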