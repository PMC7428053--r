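#' Specify one of the four diagnostic contrasts
#'
#' Each contrast maps tissue labels to a positive/negative class and an
#' aggregation unit. The two spectrum-level contrasts compare lymphocytes
#' or benign epithelium against invasive cancer. The two intraductal
#' contrasts treat `idcp` and `idcp_adj_cancer` jointly as the IDC-P class
#' and average all spectra of a core into one observation (the per-core
#' mean spectrum), since the intraductal lesion and the invasive cancer
#' adjacent to it on the same core are molecularly similar.
#'
#' @param name One of `"lymph_vs_cancer"`, `"benign_vs_cancer"`,
#'   `"idcp_vs_cancer"`, `"hgpin_vs_idcp"`.
#' @param hgpin_unit Aggregation for the HGPIN side of `hgpin_vs_idcp`:
#'   `"spectrum"` (default) or `"core_mean"`.
#' @return A list of class `contrast_spec` with `name`, `positive_class`,
#'   and a `rules` tibble (`label`, `class`, `unit`); labels absent from
#'   `rules` are excluded from the design matrix.
#' @export
contrast_spec <- function(name = c("lymph_vs_cancer", "benign_vs_cancer",
                                   "idcp_vs_cancer", "hgpin_vs_idcp"),
                          hgpin_unit = c("spectrum", "core_mean")) {
  name <- match.arg(name)
  hgpin_unit <- match.arg(hgpin_unit)
  rule <- function(label, class, unit) {
    tibble::tibble(label = label, class = class, unit = unit)
  }
  rules <- switch(
    name,
    lymph_vs_cancer = dplyr::bind_rows(
      rule("cancer", "positive", "spectrum"),
      rule("lymphocyte", "negative", "spectrum")),
    benign_vs_cancer = dplyr::bind_rows(
      rule("cancer", "positive", "spectrum"),
      rule("benign", "negative", "spectrum")),
    idcp_vs_cancer = dplyr::bind_rows(
      rule("idcp", "positive", "core_mean"),
      rule("idcp_adj_cancer", "positive", "core_mean"),
      rule("cancer", "negative", "core_mean")),
    hgpin_vs_idcp = dplyr::bind_rows(
      rule("idcp", "positive", "core_mean"),
      rule("idcp_adj_cancer", "positive", "core_mean"),
      rule("hgpin", "negative", hgpin_unit)))
  positive_class <- switch(name,
                           lymph_vs_cancer = "cancer",
                           benign_vs_cancer = "cancer",
                           idcp_vs_cancer = "idcp",
                           hgpin_vs_idcp = "idcp")
  structure(list(name = name, positive_class = positive_class, rules = rules),
            class = "contrast_spec")
}

#' Build the design matrix of a contrast
#'
#' Selects the spectra a contrast uses, aggregates core-mean classes to one
#' averaged spectrum per core, and returns the feature matrix together with
#' binary labels and patient group ids for grouped cross-validation folds.
#'
#' @param cohort A preprocessed cohort tibble.
#' @param contrast A [contrast_spec()].
#' @return A list with `x` (numeric matrix, wavenumber column names), `y`
#'   (integer 0/1, 1 = positive class), `group` (patient ids), and `info`
#'   (tibble describing each row: patient, core, unit, class, number of
#'   averaged spectra).
#' @export
build_design_matrix <- function(cohort, contrast) {
  stopifnot(inherits(contrast, "contrast_spec"))
  if (nrow(cohort) > 0L && !all(cohort$preprocessed)) {
    stop("Cohort must be preprocessed (see `preprocess_cohort()`) before ",
         "building a design matrix.", call. = FALSE)
  }
  rules <- contrast$rules
  keep <- cohort$label %in% rules$label
  sub <- cohort[keep, , drop = FALSE]
  for (cls in c("positive", "negative")) {
    if (!any(sub$label %in% rules$label[rules$class == cls])) {
      stop("Contrast ", contrast$name, ": no spectra for the ", cls,
           " class.", call. = FALSE)
    }
  }
  cls <- rules$class[match(sub$label, rules$label)]
  unit <- rules$unit[match(sub$label, rules$label)]

  rows_x <- list(); rows_info <- list()
  spectrum_rows <- which(unit == "spectrum")
  if (length(spectrum_rows) > 0L) {
    rows_x[[1]] <- sub$intensity[spectrum_rows, , drop = FALSE]
    rows_info[[1]] <- tibble::tibble(
      patient_id = sub$patient_id[spectrum_rows],
      core_id = sub$core_id[spectrum_rows],
      unit = "spectrum",
      class = cls[spectrum_rows],
      n_spectra = 1L)
  }
  core_rows <- which(unit == "core_mean")
  if (length(core_rows) > 0L) {
    cm <- tibble::tibble(patient_id = sub$patient_id[core_rows],
                         core_id = sub$core_id[core_rows],
                         class = cls[core_rows],
                         idx = core_rows)
    # a core-mean row pools every included spectrum of the core; on cores
    # carrying both idcp and adjacent cancer both map to the positive class
    grouped <- dplyr::group_by(cm, .data$patient_id, .data$core_id)
    keys <- dplyr::summarise(grouped,
                             class = .data$class[1L],
                             n_spectra = dplyr::n(),
                             idx = list(.data$idx), .groups = "drop")
    mean_x <- do.call(rbind, lapply(keys$idx, function(ii) {
      colMeans(sub$intensity[ii, , drop = FALSE])
    }))
    rows_x[[length(rows_x) + 1L]] <- mean_x
    rows_info[[length(rows_info) + 1L]] <- tibble::tibble(
      patient_id = keys$patient_id, core_id = keys$core_id,
      unit = "core_mean", class = keys$class, n_spectra = keys$n_spectra)
  }
  x <- do.call(rbind, rows_x)
  info <- dplyr::bind_rows(rows_info)
  colnames(x) <- colnames(cohort$intensity)
  list(x = x,
       y = as.integer(info$class == "positive"),
       group = info$patient_id,
       info = info)
}
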