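# Independent brute-force oracles and small fixtures shared across tests.

# Rolling-ball baseline by explicit sliding-window loops: erosion (min),
# dilation (max), boxcar mean, capped at the raw signal.
brute_rolling_ball <- function(y, r) {
  n <- length(y)
  win <- function(i) max(1L, i - r):min(n, i + r)
  eroded <- dilated <- smoothed <- numeric(n)
  for (i in seq_len(n)) eroded[i] <- min(y[win(i)])
  for (i in seq_len(n)) dilated[i] <- max(eroded[win(i)])
  for (i in seq_len(n)) smoothed[i] <- mean(dilated[win(i)])
  pmin(smoothed, y)
}

# Trapezoidal AUC over an exhaustive sweep of prediction thresholds.
brute_auc <- function(scores, labels) {
  ts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- sapply(ts, function(t) mean(scores[labels == 1] >= t))
  fpr <- sapply(ts, function(t) mean(scores[labels == 0] >= t))
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}

# Exhaustive minimal-distance-to-(0,1) operating point.
brute_operating_point <- function(scores, labels) {
  ts <- sort(unique(scores), decreasing = TRUE)
  d <- sapply(ts, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    fpr <- mean(scores[labels == 0] >= t)
    sqrt(fpr^2 + (1 - sens)^2)
  })
  list(threshold = ts[which.min(d)], distance = min(d))
}

# Cohort wrapper around an arbitrary feature matrix so pipeline functions
# can be exercised on hand-built data: one patient and core per row.
matrix_cohort <- function(x, labels, cohort_id = "toy",
                          patient_id = sprintf("p%04d", seq_len(nrow(x))),
                          preprocessed = TRUE) {
  axis <- seq(1000, by = 2, length.out = ncol(x))
  new_cohort(
    tibble::tibble(cohort_id = cohort_id, patient_id = patient_id,
                   core_id = "c1", acquisition_index = 1L, label = labels,
                   preprocessed = preprocessed, provenance = "synthetic"),
    x, axis)
}

# Two well-separated Gaussian blobs on a 2-feature axis, one patient per
# row; linearly separable by construction (10 sd separation).
separable_cohort <- function(n_per_class = 16, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * 2, 5, 1), ncol = 2),
             matrix(stats::rnorm(n_per_class * 2, 15, 1), ncol = 2))
  matrix_cohort(pmax(x, 0),
                labels = rep(c("benign", "cancer"), each = n_per_class))
}

# A quick low-resolution generator setup for structural tests.
quick_axis <- function() build_axis(600, 1700, 5)

quick_cohort <- function(n_benign = 6, n_cancer = 6, seed = 1, ...) {
  design <- cohort_design(
    "quick",
    tibble::tibble(label = c("benign", "cancer"),
                   n_patients = c(n_benign, n_cancer)),
    seed = seed, ...)
  simulate_cohort(design, spectrum_model(), quick_axis())
}

table3_recovered <- function(selected_wn, tolerance = 5) {
  ref <- default_peak_reference("benign_vs_cancer")
  sum(vapply(ref$features, function(fs)
    any(vapply(fs, function(f) any(abs(selected_wn - f) <= tolerance),
               logical(1))),
    logical(1)))
}
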