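#' Default hyperparameter grid
#'
#' Log-spaced grids inside the study ranges: feature-selection
#' regularization `fs_C` in \[0.05, 0.5\], Gaussian-SVM cost `svm_C` in
#' \[0.1, 1000\], kernel coefficient `gamma` in \[1e-4, 1e-1\], and 5-fold
#' cross-validation.
#'
#' @param fs_C,svm_C,gamma Numeric vectors of candidate values.
#' @param k_folds Number of cross-validation folds.
#' @return A list of class `hyper_grid`.
#' @export
default_grid <- function(fs_C = c(0.05, 0.1, 0.2, 0.35, 0.5),
                         svm_C = c(0.1, 1, 10, 100, 1000),
                         gamma = c(1e-4, 1e-3, 1e-2, 1e-1),
                         k_folds = 5) {
  stopifnot(all(fs_C > 0), all(svm_C > 0), all(gamma > 0), k_folds >= 2)
  structure(list(fs_C = fs_C, svm_C = svm_C, gamma = gamma,
                 k_folds = as.integer(k_folds)),
            class = "hyper_grid")
}

#' Patient-grouped, class-stratified cross-validation folds
#'
#' Assigns every patient (group) to exactly one fold so no patient's
#' spectra appear in both the training and validation side of a split;
#' within each class, groups are dealt round-robin after a seeded shuffle,
#' keeping folds class-balanced.
#'
#' @param group Group id per row (patient ids).
#' @param y Binary label per row.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer fold assignment (1..k) per row.
#' @export
make_grouped_folds <- function(group, y, k, seed = 1) {
  stopifnot(length(group) == length(y))
  # group-level class = majority class of the group's rows
  g <- tibble::tibble(group = group, y = y)
  lev <- dplyr::summarise(dplyr::group_by(g, .data$group),
                          cls = round(mean(.data$y)), .groups = "drop")
  fold_of <- with_local_seed(seed, {
    assign <- integer(nrow(lev))
    names(assign) <- lev$group
    for (cls in unique(lev$cls)) {
      members <- lev$group[lev$cls == cls]
      members <- sample(members)
      assign[members] <- rep_len(seq_len(k), length(members))
    }
    assign
  })
  folds <- unname(fold_of[group])
  for (f in seq_len(k)) {
    held <- folds == f
    if (length(unique(y[held])) < 2L || length(unique(y[!held])) < 2L) {
      stop("Stratification failure: fold ", f, " does not leave both ",
           "classes on each side of the split. Reduce `k_folds` or ",
           "enlarge the cohort.", call. = FALSE)
    }
  }
  folds
}

# Gaussian-kernel SVM wrapper around libsvm, with decision scores oriented
# so positive score means positive class.
fit_rbf_svm <- function(x, y, cost, gamma) {
  fit <- e1071::svm(x, factor(y, levels = c(0, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  # libsvm orients the decision value toward whichever class it saw first
  dv <- decision_values(fit, x[1:min(nrow(x), 20L), , drop = FALSE])
  flip <- if (grepl("^1/", attr(dv, "which"))) 1 else -1
  list(fit = fit, flip = flip)
}

decision_values <- function(fit, x) {
  pred <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  structure(drop(dv), which = colnames(dv)[1L])
}

svm_scores <- function(model, x) {
  model$flip * as.vector(decision_values(model$fit, x))
}

#' Train a contrast classifier by grid search with nested cross-validation
#'
#' For every hyperparameter combination (`fs_C`, `svm_C`, `gamma`),
#' performs k-fold cross-validation with patient-grouped, class-stratified
#' folds. Standardization and L1-SVM feature selection are refitted inside
#' each fold's training split (`nested = TRUE`, the default), so fold
#' estimates carry no leakage from the validation side; `nested = FALSE`
#' fits them once on the full training set before cross-validation, for
#' comparison. The combination with the best mean fold accuracy wins (ties
#' prefer smaller `svm_C`, then smaller `gamma`, then smaller `fs_C`, i.e.
#' fewer selected features); the final model is refitted on the complete
#' training cohort with the winning combination, and its decision threshold
#' is set at the ROC operating point (minimal distance to the upper-left
#' corner) of the training scores.
#'
#' @param cohort Preprocessed training cohort.
#' @param contrast A [contrast_spec()].
#' @param grid A [default_grid()].
#' @param seed Integer seed (fold shuffles).
#' @param nested Refit standardization and feature selection inside each
#'   fold (default) or once on the full training set.
#' @return A list of class `raman_classifier` carrying the frozen
#'   standardization statistics, feature selection, SVM fit, decision
#'   threshold, the cross-validation report (`$cv_report`), and the full
#'   grid results (`$grid_results`).
#' @export
grid_search_train <- function(cohort, contrast, grid = default_grid(),
                              seed = 1, nested = TRUE) {
  stopifnot(inherits(grid, "hyper_grid"))
  dm <- build_design_matrix(cohort, contrast)
  x <- dm$x; y <- dm$y
  k <- grid$k_folds
  folds <- make_grouped_folds(dm$group, y, k, seed = seed)

  if (!nested) {
    stats_full0 <- fit_standardization(x)
    xs_full0 <- standardize_quietly(x, stats_full0)
    sel_full0 <- lapply(grid$fs_C, function(cc)
      select_features_l1(xs_full0, y, cc))
  }

  fold_fits <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (nested) {
      st <- fit_standardization(x[tr, , drop = FALSE])
      xs_tr <- standardize_quietly(x[tr, , drop = FALSE], st)
      xs_va <- standardize_quietly(x[!tr, , drop = FALSE], st)
      sels <- lapply(grid$fs_C, function(cc)
        select_features_l1(xs_tr, y[tr], cc))
    } else {
      xs_tr <- xs_full0[tr, , drop = FALSE]
      xs_va <- xs_full0[!tr, , drop = FALSE]
      sels <- sel_full0
    }
    fold_fits[[f]] <- list(xs_tr = xs_tr, xs_va = xs_va,
                           y_tr = y[tr], y_va = y[!tr], sels = sels)
  }

  combos <- tidyr::expand_grid(fs_C = grid$fs_C, svm_C = grid$svm_C,
                               gamma = grid$gamma)
  fold_metrics <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    fs_i <- match(combos$fs_C[ci], grid$fs_C)
    m <- matrix(NA_real_, k, 4,
                dimnames = list(NULL, c("accuracy", "sensitivity",
                                        "specificity", "auc")))
    for (f in seq_len(k)) {
      ff <- fold_fits[[f]]
      sel <- ff$sels[[fs_i]]$selected_indices
      if (length(sel) == 0L) next  # no usable features at this fs_C
      model <- fit_rbf_svm(ff$xs_tr[, sel, drop = FALSE], ff$y_tr,
                           combos$svm_C[ci], combos$gamma[ci])
      sc <- svm_scores(model, ff$xs_va[, sel, drop = FALSE])
      pred <- as.integer(sc >= 0)
      cm <- confusion_and_metrics(pred, ff$y_va)
      m[f, ] <- c(cm$accuracy, cm$sensitivity, cm$specificity,
                  if (length(unique(ff$y_va)) == 2L)
                    roc_curve(sc, ff$y_va)$auc * 100 else NA_real_)
    }
    fold_metrics[[ci]] <- m
  }

  combos$mean_accuracy <- vapply(fold_metrics, function(m)
    if (all(is.na(m[, "accuracy"]))) -Inf else mean(m[, "accuracy"]),
    numeric(1))
  ord <- order(-combos$mean_accuracy, combos$svm_C, combos$gamma, combos$fs_C)
  best <- ord[1L]
  if (!is.finite(combos$mean_accuracy[best])) {
    stop("No hyperparameter combination produced a usable model ",
         "(every candidate fs_C selected zero features).", call. = FALSE)
  }

  # final model on the complete training cohort with the winning combination
  stats_full <- fit_standardization(x)
  xs_full <- apply_standardization(x, stats_full)
  selection <- select_features_l1(xs_full, y, combos$fs_C[best])
  svm_final <- fit_rbf_svm(xs_full[, selection$selected_indices,
                                   drop = FALSE],
                           y, combos$svm_C[best], combos$gamma[best])
  train_scores <- svm_scores(svm_final,
                             xs_full[, selection$selected_indices,
                                     drop = FALSE])
  roc <- roc_curve(train_scores, y)

  mbest <- fold_metrics[[best]]
  cv_report <- structure(
    list(folds = tibble::tibble(fold = seq_len(k),
                                accuracy = mbest[, "accuracy"],
                                sensitivity = mbest[, "sensitivity"],
                                specificity = mbest[, "specificity"],
                                auc = mbest[, "auc"]),
         summary = tibble::tibble(
           metric = c("accuracy", "sensitivity", "specificity", "auc"),
           mean = unname(colMeans(mbest, na.rm = TRUE)),
           sd = unname(apply(mbest, 2, stats::sd, na.rm = TRUE))),
         fs_C = combos$fs_C[best], svm_C = combos$svm_C[best],
         gamma = combos$gamma[best], k_folds = k),
    class = "cv_report")

  structure(
    list(contrast = contrast,
         wavenumbers = cohort_axis(x),
         stats = stats_full,
         selection = selection,
         svm = svm_final,
         fs_C = combos$fs_C[best],
         svm_C = combos$svm_C[best],
         gamma = combos$gamma[best],
         decision_threshold = roc$operating_point$threshold,
         training_roc = roc,
         cv_report = cv_report,
         grid_results = combos,
         seed = seed,
         nested = nested),
    class = "raman_classifier")
}

#' @export
print.raman_classifier <- function(x, ...) {
  s <- x$cv_report$summary
  cat(sprintf(paste0(
    "<raman_classifier> contrast %s\n",
    "  fs_C = %g, svm_C = %g, gamma = %g; %d features selected\n",
    "  CV accuracy %.1f +/- %.1f%%; decision threshold %.4g\n"),
    x$contrast$name, x$fs_C, x$svm_C, x$gamma,
    length(x$selection$selected_indices),
    s$mean[s$metric == "accuracy"], s$sd[s$metric == "accuracy"],
    x$decision_threshold))
  invisible(x)
}

#' Predict tissue class on a new cohort with a frozen model
#'
#' Builds the design matrix with the model's contrast, applies the stored
#' (training-cohort) standardization and feature selection without any
#' refitting, and scores each row with the Gaussian SVM. Rows are labelled
#' positive when the decision score reaches the model's decision threshold.
#'
#' @param object A `raman_classifier`.
#' @param cohort A preprocessed cohort on the same wavenumber axis as the
#'   training cohort.
#' @param ... Unused.
#' @return A tibble: row metadata, `truth` (0/1), `score`, `predicted`
#'   (0/1).
#' @export
predict.raman_classifier <- function(object, cohort, ...) {
  dm <- build_design_matrix(cohort, object$contrast)
  ax <- cohort_axis(dm$x)
  if (length(ax) != length(object$wavenumbers) ||
      max(abs(ax - object$wavenumbers)) > 1e-6) {
    stop("Wavenumber axis of the cohort does not match the training axis.",
         call. = FALSE)
  }
  xs <- standardize_quietly(dm$x, object$stats)
  sc <- svm_scores(object$svm,
                   xs[, object$selection$selected_indices, drop = FALSE])
  dplyr::mutate(dm$info,
                truth = dm$y,
                score = sc,
                predicted = as.integer(sc >= object$decision_threshold))
}
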