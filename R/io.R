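#' Write a cohort to a directory of delimited text files
#'
#' The on-disk layout mirrors common spectrometer exports: one two-column
#' TSV per spectrum (`wavenumber_cm1`, `intensity`), an `axis.tsv` holding
#' the shared grid, and a `manifest.tsv` with one row per spectrum
#' (`cohort_id`, `patient_id`, `core_id`, `acquisition_index`, `label`,
#' `file`, `preprocessed`, `provenance`). The manifest is sufficient for a
#' lossless reload with [load_cohort()].
#'
#' @param cohort A cohort tibble.
#' @param dir Destination directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  validate_cohort(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.tsv")

  axis <- if (nrow(cohort) > 0L) cohort_axis(cohort) else numeric(0)
  readr::write_tsv(tibble::tibble(wavenumber_cm1 = axis),
                   file.path(dir, "axis.tsv"))

  files <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    fname <- sprintf("%s_%s_%s_a%d.tsv",
                     sanitize_id(cohort$cohort_id[i]),
                     sanitize_id(cohort$patient_id[i]),
                     sanitize_id(cohort$core_id[i]),
                     cohort$acquisition_index[i])
    readr::write_tsv(
      tibble::tibble(wavenumber_cm1 = axis,
                     intensity = as.numeric(cohort$intensity[i, ])),
      file.path(dir, fname))
    files[i] <- fname
  }

  manifest <- tibble::tibble(
    cohort_id = cohort$cohort_id,
    patient_id = cohort$patient_id,
    core_id = cohort$core_id,
    acquisition_index = cohort$acquisition_index,
    label = cohort$label,
    file = files,
    preprocessed = cohort$preprocessed,
    provenance = cohort$provenance)
  readr::write_tsv(manifest, manifest_path)
  invisible(manifest_path)
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]", "-", x)

#' Load a cohort from a manifest
#'
#' Reads the manifest written by [save_cohort()] and the spectrum files it
#' references. Spectra whose stored axis differs from the manifest axis are
#' linearly interpolated onto it; interpolation never extrapolates, so a
#' manifest axis extending beyond a file's range is an error. Files flagged
#' as interpolated are recorded in the `interpolated` attribute of the
#' result.
#'
#' @param manifest_path Path to a `manifest.tsv`.
#' @return A cohort tibble.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("Manifest not found: ", manifest_path, call. = FALSE)
  }
  dir <- dirname(manifest_path)
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  required <- c("cohort_id", "patient_id", "core_id", "acquisition_index",
                "label", "file", "preprocessed")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0L) {
    stop("Manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("provenance" %in% names(manifest))) manifest$provenance <- "imported"
  manifest$cohort_id <- as.character(manifest$cohort_id)
  manifest$patient_id <- as.character(manifest$patient_id)
  manifest$core_id <- as.character(manifest$core_id)
  manifest$label <- as.character(manifest$label)

  key <- paste(manifest$cohort_id, manifest$patient_id, manifest$core_id,
               manifest$acquisition_index, sep = "/")
  if (anyDuplicated(key)) {
    stop("Manifest contains a duplicate (cohort, patient, core, acquisition) ",
         "key: ", key[duplicated(key)][1L], call. = FALSE)
  }

  axis_file <- file.path(dir, "axis.tsv")
  axis <- if (file.exists(axis_file)) {
    readr::read_tsv(axis_file, show_col_types = FALSE,
                    progress = FALSE)$wavenumber_cm1
  } else {
    NULL
  }

  if (nrow(manifest) == 0L) {
    return(new_cohort(manifest[required[1:5]],
                      matrix(numeric(0), nrow = 0,
                             ncol = length(axis %||% numeric(0))),
                      axis %||% numeric(0)))
  }

  spectra <- vector("list", nrow(manifest))
  interpolated <- character(0)
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, manifest$file[i])
    if (!file.exists(path)) {
      stop("Spectrum file referenced by manifest is missing: ",
           manifest$file[i], call. = FALSE)
    }
    sp <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (is.null(axis)) axis <- sp$wavenumber_cm1
    if (length(sp$wavenumber_cm1) == length(axis) &&
        max(abs(sp$wavenumber_cm1 - axis)) < 1e-6) {
      spectra[[i]] <- sp$intensity
    } else {
      if (min(axis) < min(sp$wavenumber_cm1) - 1e-9 ||
          max(axis) > max(sp$wavenumber_cm1) + 1e-9) {
        stop("Axis of ", manifest$file[i], " does not cover the manifest ",
             "axis; interpolation never extrapolates.", call. = FALSE)
      }
      spectra[[i]] <- stats::approx(sp$wavenumber_cm1, sp$intensity,
                                    xout = axis, rule = 1)$y
      interpolated <- c(interpolated, manifest$file[i])
    }
  }

  cohort <- new_cohort(manifest[c(required[1:5], "preprocessed", "provenance")],
                       do.call(rbind, spectra), axis)
  attr(cohort, "interpolated") <- interpolated
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
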