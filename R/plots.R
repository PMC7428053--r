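#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve with its operating point
#'
#' @param object A `raman_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot raman_roc
#' @export
autoplot.raman_roc <- function(object, ...) {
  op <- object$operating_point
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = 1 - op$specificity, y = op$sensitivity,
                      colour = "red", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot class-mean spectra of a cohort
#'
#' @param object A cohort tibble.
#' @param ... Unused.
#' @return A ggplot of mean intensity per tissue label across the axis.
#' @method autoplot raman_cohort
#' @export
autoplot.raman_cohort <- function(object, ...) {
  ax <- cohort_axis(object)
  means <- purrr::map_dfr(unique(object$label), function(lb) {
    tibble::tibble(
      label = lb, wavenumber_cm1 = ax,
      intensity = colMeans(object$intensity[object$label == lb, ,
                                            drop = FALSE]))
  })
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$wavenumber_cm1,
                               y = .data$intensity, colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Intensity (a.u.)", colour = "Tissue") +
    ggplot2::theme_minimal()
}

#' Plot the selected feature weights of a classifier
#'
#' Stem plot of the L1-SVM weights against wavenumber; positive weights
#' pull toward the positive class of the contrast.
#'
#' @param object A `raman_classifier`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot raman_classifier
#' @export
autoplot.raman_classifier <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber_cm1,
                                   y = .data$weight)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$wavenumber_cm1,
                                       yend = 0)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "L1-SVM weight",
                  title = object$contrast$name) +
    ggplot2::theme_minimal()
}
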