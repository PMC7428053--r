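#' Build a regular wavenumber axis
#'
#' Constructs the shared Raman-shift grid on which all spectra of a cohort
#' live. The grid starts at `start_cm1` and advances in steps of `step_cm1`;
#' the last point is the largest grid point not exceeding `end_cm1`, so the
#' stored axis never overshoots the instrument range.
#'
#' The default arguments reproduce a 602--1726 cm^-1 window at ~1.1 cm^-1
#' resolution, the fingerprint region covered by a 1,200 lines/mm grating on
#' a confocal Raman microscope, which yields slightly over 1,000 spectral
#' features.
#'
#' @param start_cm1 First Raman shift of the grid (cm^-1).
#' @param end_cm1 Upper bound of the grid (cm^-1); must exceed `start_cm1`.
#' @param step_cm1 Grid spacing (cm^-1); must be positive.
#'
#' @return A numeric vector of class `raman_axis`: strictly increasing,
#'   regularly spaced Raman shifts in cm^-1, with attributes `start_cm1`,
#'   `end_cm1` and `step_cm1`.
#' @examples
#' ax <- build_axis()
#' length(ax)       # > 1000 features
#' head(ax)
#' @export
build_axis <- function(start_cm1 = 602, end_cm1 = 1726, step_cm1 = 1.1) {
  if (!is.numeric(start_cm1) || !is.numeric(end_cm1) || !is.numeric(step_cm1) ||
      length(start_cm1) != 1L || length(end_cm1) != 1L || length(step_cm1) != 1L) {
    stop("`start_cm1`, `end_cm1` and `step_cm1` must be single numbers.",
         call. = FALSE)
  }
  if (!(start_cm1 < end_cm1)) {
    stop("`start_cm1` must be strictly smaller than `end_cm1`.", call. = FALSE)
  }
  if (!(step_cm1 > 0)) {
    stop("`step_cm1` must be strictly positive.", call. = FALSE)
  }
  n_points <- floor((end_cm1 - start_cm1) / step_cm1) + 1L
  grid <- start_cm1 + (seq_len(n_points) - 1L) * step_cm1
  structure(grid,
            start_cm1 = start_cm1, end_cm1 = end_cm1, step_cm1 = step_cm1,
            class = "raman_axis")
}

#' @export
print.raman_axis <- function(x, ...) {
  cat(sprintf("<raman_axis> %d points, %.6g to %.6g cm^-1, step %.6g cm^-1\n",
              length(x), x[[1L]], x[[length(x)]], attr(x, "step_cm1")))
  invisible(x)
}

# Format a wavenumber for use as a matrix column name; 10 significant
# digits round-trip the grid well beyond the 6 digits the on-disk format
# guarantees.
format_wavenumber <- function(wn) sprintf("%.10g", wn)

#' Recover the wavenumber axis of an intensity matrix or cohort
#'
#' The axis travels with the data as the column names of the intensity
#' matrix, so it survives any dplyr manipulation of the cohort tibble.
#'
#' @param x A cohort tibble (see [simulate_cohort()]) or an intensity matrix
#'   whose column names are wavenumbers.
#' @return Numeric vector of wavenumbers (cm^-1).
#' @export
cohort_axis <- function(x) {
  m <- if (is.matrix(x)) x else x$intensity
  if (is.null(m) || is.null(colnames(m))) {
    stop("No wavenumber axis found: expected an `intensity` matrix column ",
         "with wavenumber column names.", call. = FALSE)
  }
  as.numeric(colnames(m))
}

#' Tissue labels recognized by the pipeline
#'
#' The closed set of tissue classes annotated on tissue-microarray cores:
#' lymphocyte clusters, benign epithelium, invasive prostate cancer,
#' intraductal carcinoma of the prostate (IDC-P), invasive cancer adjacent
#' to IDC-P on the same core, and high-grade prostatic intraepithelial
#' neoplasia (HGPIN).
#'
#' @return Character vector of the six valid labels.
#' @export
tissue_labels <- function() {
  c("lymphocyte", "benign", "cancer", "idcp", "idcp_adj_cancer", "hgpin")
}
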