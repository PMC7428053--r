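#' Rolling-ball baseline of a single spectrum
#'
#' One-dimensional rolling-ball background estimation: grayscale erosion
#' (running minimum) followed by dilation (running maximum) with a
#' structuring element of half-width `radius_points` grid points — the
#' morphological opening — followed by a boxcar smoothing pass with the
#' same window. Windows are truncated at the spectrum edges. The smoothed
#' opening is finally capped at the raw signal so the baseline never
#' exceeds it at any grid point.
#'
#' @param y Numeric intensity vector (raw spectrum).
#' @param radius_points Structuring-element half-width in grid points
#'   (default 50, about 55 cm^-1 at 1.1 cm^-1 spacing: wide relative to a
#'   12 cm^-1 Raman line, narrow relative to fluorescence).
#' @return Numeric baseline vector of the same length.
#' @export
rolling_ball_baseline <- function(y, radius_points = 50) {
  n <- length(y)
  if (radius_points < 1 || radius_points != round(radius_points)) {
    stop("`radius_points` must be a positive integer.", call. = FALSE)
  }
  if (radius_points >= n) {
    stop("`radius_points` must be smaller than the spectrum length (",
         n, ").", call. = FALSE)
  }
  eroded <- running_extreme(y, radius_points, min)
  opened <- running_extreme(eroded, radius_points, max)
  pmin(running_mean(opened, radius_points), y)
}

running_extreme <- function(y, r, fun) {
  n <- length(y)
  vapply(seq_len(n),
         function(i) fun(y[max(1L, i - r):min(n, i + r)]),
         numeric(1))
}

# Centered running mean with truncated edge windows, via cumulative sums.
running_mean <- function(y, r) {
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - r, 1L)
  hi <- pmin(seq_len(n) + r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Rolling-ball correction of one spectrum
#'
#' @inheritParams rolling_ball_baseline
#' @param clip_negative Clip the corrected signal at zero (Raman
#'   intensities are physically non-negative).
#' @return List with `corrected`, `baseline`, and `radius_points`.
#' @export
rolling_ball_correct <- function(y, radius_points = 50, clip_negative = TRUE) {
  baseline <- rolling_ball_baseline(y, radius_points)
  corrected <- y - baseline
  if (clip_negative) corrected <- pmax(corrected, 0)
  list(corrected = corrected, baseline = baseline,
       radius_points = radius_points)
}

#' Remove substrate and fluorescence background from a cohort
#'
#' Applies [rolling_ball_correct()] to every spectrum and flags the cohort
#' preprocessed. Already-preprocessed cohorts pass through unchanged with a
#' warning unless `reprocess = TRUE`.
#'
#' @param cohort A cohort tibble.
#' @inheritParams rolling_ball_correct
#' @param reprocess Apply the correction again even if the cohort is
#'   already flagged preprocessed.
#' @return The corrected cohort (`preprocessed = TRUE`).
#' @export
preprocess_cohort <- function(cohort, radius_points = 50,
                              clip_negative = TRUE, reprocess = FALSE) {
  if (nrow(cohort) > 0L && all(cohort$preprocessed)) {
    if (!reprocess) {
      warning("Cohort is already preprocessed; returning it unchanged. ",
              "Use `reprocess = TRUE` to correct again.", call. = FALSE)
      return(cohort)
    }
    warning("Cohort is already preprocessed; correcting again as requested.",
            call. = FALSE)
  }
  out <- cohort
  for (i in seq_len(nrow(out))) {
    out$intensity[i, ] <- rolling_ball_correct(
      as.numeric(cohort$intensity[i, ]), radius_points,
      clip_negative)$corrected
  }
  out$preprocessed <- TRUE
  out
}

#' Fit per-feature standardization statistics
#'
#' Computes the per-wavenumber sample mean and standard deviation over a
#' set of (training) spectra. These statistics are fitted once on the
#' training cohort and reused unchanged on testing cohorts, so no
#' information leaks from test data into the model.
#'
#' @param x A preprocessed cohort tibble or a numeric matrix (rows =
#'   spectra).
#' @return A list of class `standardization_stats` with `mean`, `sd`
#'   (sample sd, denominator n-1), and `fitted_on`.
#' @export
fit_standardization <- function(x) {
  fitted_on <- NA_character_
  if (inherits(x, "raman_cohort") || is.data.frame(x)) {
    fitted_on <- paste(unique(x$cohort_id), collapse = "+")
    x <- x$intensity
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop("Standardization needs at least 2 spectra.", call. = FALSE)
  }
  structure(list(mean = colMeans(x),
                 sd = apply(x, 2, stats::sd),
                 fitted_on = fitted_on,
                 wavenumbers = colnames(x)),
            class = "standardization_stats")
}

#' Standardize spectra with previously fitted statistics
#'
#' Centers and scales each feature with the training mean and standard
#' deviation. Features that were constant in training (zero sd) are mapped
#' to 0 with a warning rather than dividing by zero.
#'
#' @param x A cohort tibble or numeric matrix.
#' @param stats A `standardization_stats` object from
#'   [fit_standardization()].
#' @return A numeric feature matrix (rows = spectra, columns =
#'   wavenumbers).
#' @export
apply_standardization <- function(x, stats) {
  if (inherits(x, "raman_cohort") || is.data.frame(x)) x <- x$intensity
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mean)) {
    stop("Feature count mismatch: matrix has ", ncol(x),
         " columns but statistics were fitted on ", length(stats$mean), ".",
         call. = FALSE)
  }
  sd <- stats$sd
  constant <- sd == 0
  if (any(constant)) {
    warning(sum(constant), " constant feature(s) in the training set were ",
            "standardized to 0.", call. = FALSE)
    sd[constant] <- 1
  }
  out <- sweep(sweep(x, 2, stats$mean, "-"), 2, sd, "/")
  out[, constant] <- 0
  out
}

# Internal: standardize without repeating the constant-feature warning;
# used where the same statistics are applied many times (fold loops,
# prediction with an already-fitted model).
standardize_quietly <- function(x, stats) {
  withCallingHandlers(
    apply_standardization(x, stats),
    warning = function(w) {
      if (grepl("constant feature", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}
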