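#' Assemble a cohort tibble from metadata and an intensity matrix
#'
#' A cohort is the unit of training and testing: a tibble with one row per
#' acquired spectrum, metadata columns identifying where the spectrum came
#' from, and a matrix column `intensity` holding the spectra (rows align
#' with tibble rows; matrix column names are the wavenumber axis).
#'
#' @param meta Data frame with columns `cohort_id`, `patient_id`, `core_id`,
#'   `acquisition_index`, `label`; optionally `preprocessed` (default FALSE)
#'   and `provenance` (default "imported").
#' @param intensity Numeric matrix, `nrow(meta)` rows, one column per axis
#'   point, non-negative, no missing values.
#' @param axis Wavenumber axis (numeric vector) for the matrix columns.
#'
#' @return A tibble of class `raman_cohort`.
#' @export
new_cohort <- function(meta, intensity, axis) {
  meta <- tibble::as_tibble(meta)
  required <- c("cohort_id", "patient_id", "core_id", "acquisition_index", "label")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("Cohort metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("preprocessed" %in% names(meta))) meta$preprocessed <- FALSE
  if (!("provenance" %in% names(meta))) meta$provenance <- "imported"
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != nrow(meta)) {
    stop("`intensity` must have one row per metadata row.", call. = FALSE)
  }
  if (ncol(intensity) != length(axis)) {
    stop("`intensity` must have one column per axis point.", call. = FALSE)
  }
  colnames(intensity) <- format_wavenumber(as.numeric(axis))
  out <- meta[, c("cohort_id", "patient_id", "core_id", "acquisition_index",
                  "label", "preprocessed", "provenance")]
  out$acquisition_index <- as.integer(out$acquisition_index)
  out$intensity <- intensity
  class(out) <- c("raman_cohort", class(tibble::tibble()))
  validate_cohort(out)
}

#' Validate cohort invariants
#'
#' Checks that labels are in the closed tissue set, acquisition keys are
#' unique, acquisition indices are in 1..4, per-patient core counts are in
#' 1..6, intensities are finite and non-negative, and that any core carrying
#' IDC-P spectra also carries adjacent-cancer spectra (and vice versa),
#' mirroring how intraductal carcinoma is annotated together with the
#' invasive cancer surrounding it on the same core.
#'
#' @param cohort A cohort tibble.
#' @return The cohort, invisibly unchanged, or an error.
#' @export
validate_cohort <- function(cohort) {
  bad <- setdiff(unique(cohort$label), tissue_labels())
  if (length(bad) > 0L) {
    stop("Unknown tissue label(s): ", paste(bad, collapse = ", "),
         ". Valid labels: ", paste(tissue_labels(), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(cohort$cohort_id, cohort$patient_id, cohort$core_id,
               cohort$acquisition_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("Duplicate (cohort, patient, core, acquisition) key: ",
         gsub("\r", "/", dup), call. = FALSE)
  }
  if (nrow(cohort) > 0L) {
    if (any(cohort$acquisition_index < 1L | cohort$acquisition_index > 4L)) {
      stop("`acquisition_index` must lie in 1..4.", call. = FALSE)
    }
    core_per_patient <- dplyr::distinct(
      tibble::as_tibble(cohort)[c("patient_id", "core_id")])
    n_cores <- table(core_per_patient$patient_id)
    if (any(n_cores > 6L)) {
      stop("A patient may carry at most 6 cores; offending patient: ",
           names(n_cores)[which(n_cores > 6L)[1L]], call. = FALSE)
    }
    if (anyNA(cohort$intensity) || any(!is.finite(cohort$intensity))) {
      stop("Intensities must be finite with no missing values.", call. = FALSE)
    }
    if (any(cohort$intensity < 0)) {
      stop("Intensities must be non-negative.", call. = FALSE)
    }
    idcp_cores <- unique(paste(cohort$patient_id, cohort$core_id)[
      cohort$label == "idcp"])
    adj_cores <- unique(paste(cohort$patient_id, cohort$core_id)[
      cohort$label == "idcp_adj_cancer"])
    if (!setequal(idcp_cores, adj_cores)) {
      stop("Every core with IDC-P spectra must also carry adjacent-cancer ",
           "spectra on the same core, and conversely.", call. = FALSE)
    }
  }
  invisible(cohort)
}

#' @export
print.raman_cohort <- function(x, ...) {
  ax <- tryCatch(cohort_axis(x), error = function(e) NULL)
  cat(sprintf("<raman_cohort> %s: %d spectra, %d patients%s\n",
              paste(unique(x$cohort_id), collapse = "+"),
              nrow(x), length(unique(x$patient_id)),
              if (is.null(ax)) "" else
                sprintf(", %d features (%.6g-%.6g cm^-1)",
                        length(ax), min(ax), max(ax))))
  if (nrow(x) > 0L) {
    tab <- table(x$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  NextMethod()
}
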