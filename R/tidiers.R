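#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the selected features of a trained classifier
#'
#' @param x A `raman_classifier`.
#' @param ... Unused.
#' @return Tibble with one row per selected feature: `wavenumber_cm1`,
#'   `weight` (L1-SVM weight, sign indicates the favored class), and
#'   `index`.
#' @method tidy raman_classifier
#' @export
tidy.raman_classifier <- function(x, ...) {
  tibble::tibble(wavenumber_cm1 = x$selection$selected_wavenumbers_cm1,
                 weight = x$selection$weights,
                 index = x$selection$selected_indices)
}

#' One-row model summary
#'
#' @param x A `raman_classifier`.
#' @param ... Unused.
#' @return One-row tibble: contrast, chosen hyperparameters, selected
#'   feature count, cross-validated accuracy mean/sd (percent), AUC mean,
#'   and decision threshold.
#' @method glance raman_classifier
#' @export
glance.raman_classifier <- function(x, ...) {
  s <- x$cv_report$summary
  tibble::tibble(contrast = x$contrast$name,
                 fs_C = x$fs_C, svm_C = x$svm_C, gamma = x$gamma,
                 n_selected = length(x$selection$selected_indices),
                 cv_accuracy = s$mean[s$metric == "accuracy"],
                 cv_accuracy_sd = s$sd[s$metric == "accuracy"],
                 cv_auc = s$mean[s$metric == "auc"],
                 decision_threshold = x$decision_threshold)
}

#' @describeIn roc_curve Tidy the ROC points.
#' @param x A `raman_roc`.
#' @param ... Unused.
#' @method tidy raman_roc
#' @export
tidy.raman_roc <- function(x, ...) x$points

#' @describeIn roc_curve One-row AUC and operating-point summary.
#' @method glance raman_roc
#' @export
glance.raman_roc <- function(x, ...) {
  op <- x$operating_point
  tibble::tibble(auc = x$auc, threshold = op$threshold,
                 sensitivity = op$sensitivity, specificity = op$specificity,
                 distance = op$distance)
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The per-fold metrics tibble.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @describeIn tidy.cv_report Fold-averaged summary with chosen
#'   hyperparameters.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  s <- tidyr::pivot_wider(x$summary, names_from = "metric",
                          values_from = c("mean", "sd"))
  dplyr::mutate(s, fs_C = x$fs_C, svm_C = x$svm_C, gamma = x$gamma,
                k_folds = x$k_folds)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds; fs_C = %g, svm_C = %g, gamma = %g\n",
              x$k_folds, x$fs_C, x$svm_C, x$gamma))
  print(x$summary)
  invisible(x)
}
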