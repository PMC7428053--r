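#' ROC curve, AUC, and the upper-left operating point
#'
#' Sweeps every distinct score value as a threshold (ties enter and leave
#' the positive set together), computes sensitivity and specificity at
#' each, the area under the curve by the trapezoidal rule, and the
#' operating point: the threshold whose (1 - specificity, sensitivity)
#' point has minimal Euclidean distance to the upper-left corner (0, 1).
#'
#' @param scores Numeric decision scores (larger = more positive).
#' @param labels Binary truth (0/1, logical, or two-level factor).
#' @return A list of class `raman_roc`: `points` (tibble with `threshold`,
#'   `sensitivity`, `specificity`, `fpr`), `auc` (in \[0, 1\]), and
#'   `operating_point` (`threshold`, `sensitivity`, `specificity`,
#'   `distance`).
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(to_pm1(labels) == 1)
  if (length(scores) != length(y)) {
    stop("`scores` and `labels` lengths differ.", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("ROC needs both classes present.", call. = FALSE)
  }
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thresholds, function(t) sum(scores >= t & y == 1L) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores < t & y == 0L) / n_neg,
                 numeric(1))
  points <- tibble::tibble(threshold = c(Inf, thresholds),
                           sensitivity = c(0, sens),
                           specificity = c(1, spec),
                           fpr = 1 - c(1, spec))
  auc <- sum(diff(points$fpr) *
               (utils::head(points$sensitivity, -1) +
                  utils::tail(points$sensitivity, -1)) / 2)
  finite <- is.finite(points$threshold)
  dist <- sqrt(points$fpr^2 + (1 - points$sensitivity)^2)
  best <- which(finite)[which.min(dist[finite])]
  structure(list(points = points,
                 auc = auc,
                 operating_point = list(threshold = points$threshold[best],
                                        sensitivity = points$sensitivity[best],
                                        specificity = points$specificity[best],
                                        distance = dist[best])),
            class = "raman_roc")
}

#' @export
print.raman_roc <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf(paste0("<raman_roc> AUC %.3f; operating point: threshold ",
                     "%.4g, sensitivity %.3f, specificity %.3f\n"),
              x$auc, op$threshold, op$sensitivity, op$specificity))
  invisible(x)
}

#' Confusion matrix and summary metrics
#'
#' Cross-tabulates binary predictions against truth and derives accuracy,
#' sensitivity and specificity as percentages.
#'
#' @param predicted,truth Binary vectors of equal length (1 = positive).
#' @param row_unit What one row represents: `"spectrum"` or `"core"`
#'   (recorded in the output, not used in computation).
#' @return A list of class `raman_confusion`: `tp`, `fp`, `fn`, `tn`,
#'   `table` (2x2 matrix, rows = truth, columns = predicted), `row_unit`,
#'   and `accuracy`, `sensitivity`, `specificity` in percent.
#' @export
confusion_and_metrics <- function(predicted, truth,
                                  row_unit = c("spectrum", "core")) {
  row_unit <- match.arg(row_unit)
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` lengths differ.", call. = FALSE)
  }
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  tn <- sum(predicted == 0L & truth == 0L)
  tab <- matrix(c(tp, fn, fp, tn), 2, 2,
                dimnames = list(truth = c("positive", "negative"),
                                predicted = c("positive", "negative")))
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, table = tab,
                 row_unit = row_unit,
                 accuracy = 100 * (tp + tn) / max(1L, length(truth)),
                 sensitivity = 100 * tp / max(1L, tp + fn),
                 specificity = 100 * tn / max(1L, tn + fp)),
            class = "raman_confusion")
}

#' @export
print.raman_confusion <- function(x, ...) {
  cat(sprintf(paste0("<raman_confusion> (%s level) accuracy %.1f%%, ",
                     "sensitivity %.1f%%, specificity %.1f%%\n"),
              x$row_unit, x$accuracy, x$sensitivity, x$specificity))
  print(x$table)
  invisible(x)
}

#' Assign selected wavenumbers to reference Raman peaks
#'
#' Matches each selected wavenumber to the nearest reference peak center
#' within a tolerance. Centers given as ranges count distance zero inside
#' the range and the distance to the nearest endpoint outside it.
#'
#' @param selection A `feature_selection` object or a numeric vector of
#'   wavenumbers (cm^-1).
#' @param reference Peak reference tibble, as from
#'   [default_peak_reference()].
#' @param tolerance_cm1 Maximal distance (cm^-1) for a match; the default 8
#'   covers most feature-to-center spreads, while 15 also captures wide
#'   offsets such as a 1,470 cm^-1 feature on the 1,484 cm^-1 band.
#' @return A tibble with one row per selected wavenumber: `selected_cm1`,
#'   `matched`, `distance_cm1`, and the matched entry's `contrast`,
#'   `feature_cm1`, center bounds, `increased_in`, `vibrational_mode`,
#'   `molecules` (NA when unmatched).
#' @export
assign_peaks <- function(selection, reference = default_peak_reference(),
                         tolerance_cm1 = 8) {
  stopifnot(tolerance_cm1 > 0)
  if (nrow(reference) == 0L) {
    stop("Peak reference table is empty.", call. = FALSE)
  }
  wns <- if (inherits(selection, "feature_selection")) {
    selection$selected_wavenumbers_cm1
  } else {
    as.numeric(selection)
  }
  purrr::map_dfr(wns, function(w) {
    d <- pmax(0, pmax(reference$center_lo_cm1 - w,
                      w - reference$center_hi_cm1))
    i <- which.min(d)
    if (d[i] <= tolerance_cm1) {
      tibble::tibble(selected_cm1 = w, matched = TRUE, distance_cm1 = d[i],
                     contrast = reference$contrast[i],
                     feature_cm1 = reference$feature_cm1[i],
                     center_lo_cm1 = reference$center_lo_cm1[i],
                     center_hi_cm1 = reference$center_hi_cm1[i],
                     increased_in = reference$increased_in[i],
                     vibrational_mode = reference$vibrational_mode[i],
                     molecules = reference$molecules[i])
    } else {
      tibble::tibble(selected_cm1 = w, matched = FALSE,
                     distance_cm1 = d[i],
                     contrast = NA_character_, feature_cm1 = NA_character_,
                     center_lo_cm1 = NA_real_, center_hi_cm1 = NA_real_,
                     increased_in = NA_character_,
                     vibrational_mode = NA_character_,
                     molecules = NA_character_)
    }
  })
}

#' Evaluate a frozen classifier on a cohort
#'
#' Predicts every row, then reports threshold-free discrimination (ROC and
#' AUC) together with the confusion matrix and metrics at the model's
#' decision threshold.
#'
#' @param model A `raman_classifier`.
#' @param cohort A preprocessed cohort.
#' @return A list of class `evaluation_report`: `predictions`, `roc`,
#'   `confusion`, and a one-row `metrics` tibble (percent scale).
#' @export
evaluate_classifier <- function(model, cohort) {
  pred <- stats::predict(model, cohort)
  roc <- roc_curve(pred$score, pred$truth)
  row_unit <- if (all(pred$unit == "core_mean")) "core" else "spectrum"
  cm <- confusion_and_metrics(pred$predicted, pred$truth, row_unit)
  metrics <- tibble::tibble(
    contrast = model$contrast$name,
    cohort = paste(unique(cohort$cohort_id), collapse = "+"),
    row_unit = row_unit,
    n = nrow(pred),
    accuracy = cm$accuracy,
    sensitivity = cm$sensitivity,
    specificity = cm$specificity,
    auc = 100 * roc$auc,
    threshold = model$decision_threshold)
  structure(list(predictions = pred, roc = roc, confusion = cm,
                 metrics = metrics),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$metrics)
  invisible(x)
}
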