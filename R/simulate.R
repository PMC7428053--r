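#' Spectrum generator model for synthetic tissue Raman spectra
#'
#' Defines the generative model used by [simulate_spectrum()] and
#' [simulate_cohort()]: a smooth fluorescence baseline (degree-4 polynomial
#' over the axis) plus one broad Gaussian for the aluminum-substrate
#' contribution, a shared set of prostate-tissue Raman peaks (Gaussian
#' lines), class-conditional amplitude shifts at the discriminative
#' wavenumbers of the packaged peak reference, per-spectrum multiplicative
#' log-normal amplitude jitter (patient/core heterogeneity), and additive
#' Gaussian noise (shot/read noise).
#'
#' Class effects are planted additively: for each reference entry, every
#' listed feature wavenumber receives a Gaussian component of amplitude
#' `effect_size * effect_ref_amplitude`, positive for the tissue class the
#' entry reports as increased and negative for the opposite class of that
#' contrast. IDC-P effects are applied to both `idcp` and
#' `idcp_adj_cancer`, reflecting the molecular similarity of intraductal
#' carcinoma and the invasive cancer adjacent to it. Lymphocytes receive a
#' fixed nucleic-acid-rich signature (stronger DNA backbone and ring bands,
#' weaker lipid/amide bands) so the lymphocyte contrast is learnable.
#'
#' @param peak_reference Reference table, as from [default_peak_reference()].
#' @param effect_size Relative amplitude shift at discriminative
#'   wavenumbers (dimensionless; 0.25 plants +/-25 percent of
#'   `effect_ref_amplitude`).
#' @param effect_ref_amplitude Amplitude scale (arbitrary units) of planted
#'   class-effect components; comparable to a mid-size tissue peak.
#' @param noise_sd Additive per-point Gaussian noise standard deviation
#'   (arbitrary units).
#' @param amplitude_cv Coefficient of variation of the per-spectrum
#'   log-normal peak-amplitude jitter (unit mean).
#' @param peak_fwhm_cm1 Full width at half maximum of tissue Raman lines
#'   (cm^-1).
#' @param fluor_amplitude,substrate_amplitude Baseline amplitudes
#'   (arbitrary units) of the fluorescence polynomial and the substrate
#'   Gaussian (center 900 cm^-1, FWHM 600 cm^-1).
#' @return A list of class `spectrum_model`.
#' @export
spectrum_model <- function(peak_reference = default_peak_reference(),
                           effect_size = 0.25,
                           effect_ref_amplitude = 40,
                           noise_sd = 2,
                           amplitude_cv = 0.1,
                           peak_fwhm_cm1 = 12,
                           fluor_amplitude = 400,
                           substrate_amplitude = 150) {
  stopifnot(effect_size >= 0, noise_sd >= 0, amplitude_cv >= 0,
            peak_fwhm_cm1 > 0, effect_ref_amplitude >= 0)
  base_peaks <- tibble::tibble(
    center_cm1 = c(622, 643, 720, 759, 785, 828, 853, 880, 936, 1003, 1031,
                   1093, 1127, 1171, 1207, 1246, 1263, 1302, 1338, 1448,
                   1484, 1553, 1578, 1607, 1657),
    amplitude = c(15, 12, 25, 20, 15, 25, 30, 18, 25, 100, 35,
                  25, 20, 18, 20, 35, 30, 35, 30, 60,
                  25, 20, 15, 20, 70))

  effects <- class_effects(peak_reference, effect_size * effect_ref_amplitude)
  # lymphocyte signature: nucleic-acid rich, lipid/protein poor
  effects <- dplyr::bind_rows(
    effects,
    tibble::tibble(
      label = "lymphocyte",
      center_cm1 = c(785, 1093, 1338, 1578, 1448, 1657),
      delta_amplitude = c(20, 15, 10, 15, -20, -25)))

  structure(
    list(base_peaks = base_peaks,
         effects = effects,
         effect_size = effect_size,
         effect_ref_amplitude = effect_ref_amplitude,
         noise_sd = noise_sd,
         amplitude_cv = amplitude_cv,
         peak_fwhm_cm1 = peak_fwhm_cm1,
         fluor_amplitude = fluor_amplitude,
         substrate_amplitude = substrate_amplitude),
    class = "spectrum_model")
}

# Expand the reference table into per-label additive amplitude deltas.
# `increased_in` tags name one side of a two-class contrast; the opposite
# side receives the mirrored (negative) delta. The idcp tag covers both the
# idcp and idcp_adj_cancer labels.
class_effects <- function(reference, delta) {
  other_side <- list(
    benign_vs_cancer = c(benign = "cancer", cancer = "benign"),
    idcp_vs_cancer = c(idcp = "cancer", cancer = "idcp"),
    hgpin_vs_idcp = c(hgpin = "idcp", idcp = "hgpin"))
  expand_tag <- function(tag) if (tag == "idcp") c("idcp", "idcp_adj_cancer") else tag
  purrr::pmap_dfr(reference, function(contrast, feature_cm1, features,
                                      center_lo_cm1, center_hi_cm1,
                                      increased_in, ...) {
    down <- unname(other_side[[contrast]][increased_in])
    dplyr::bind_rows(
      tidyr::expand_grid(label = expand_tag(increased_in),
                         center_cm1 = features, delta_amplitude = delta),
      tidyr::expand_grid(label = expand_tag(down),
                         center_cm1 = features, delta_amplitude = -delta))
  })
}

gaussian_line <- function(axis, center, amplitude, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  amplitude * exp(-((as.numeric(axis) - center)^2) / (2 * sigma^2))
}

model_baseline <- function(model, axis) {
  x <- as.numeric(axis)
  if (length(x) == 0L) return(numeric(0))
  t <- (x - min(x)) / max(max(x) - min(x), 1)
  fluor <- model$fluor_amplitude *
    (1 - 0.9 * t + 0.5 * t^2 - 0.2 * t^3 + 0.05 * t^4)
  substrate <- gaussian_line(x, 900, model$substrate_amplitude, 600)
  fluor + substrate
}

# Sum of Gaussian peak components (shared tissue peaks + class effects)
# for one tissue label, noise- and jitter-free.
model_peak_profile <- function(model, label, axis) {
  x <- as.numeric(axis)
  peaks <- model$base_peaks
  eff <- model$effects[model$effects$label == label, ]
  profile <- numeric(length(x))
  for (i in seq_len(nrow(peaks))) {
    profile <- profile + gaussian_line(x, peaks$center_cm1[i],
                                       peaks$amplitude[i],
                                       model$peak_fwhm_cm1)
  }
  for (i in seq_len(nrow(eff))) {
    profile <- profile + gaussian_line(x, eff$center_cm1[i],
                                       eff$delta_amplitude[i],
                                       model$peak_fwhm_cm1)
  }
  profile
}

# Evaluate code with a private RNG state so simulation never disturbs the
# caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one tissue Raman spectrum
#'
#' Draws a single synthetic acquisition: baseline plus the label's peak
#' profile scaled by log-normal jitter, plus additive Gaussian noise,
#' clipped at zero. Deterministic given `seed`.
#'
#' @param model A [spectrum_model()].
#' @param label Tissue label (one of [tissue_labels()]).
#' @param axis Wavenumber axis from [build_axis()].
#' @param seed Integer seed for this spectrum.
#' @return Numeric intensity vector of `length(axis)`.
#' @export
simulate_spectrum <- function(model, label, axis, seed) {
  if (!(label %in% tissue_labels())) {
    stop("No amplitude map for label '", label, "'; valid labels: ",
         paste(tissue_labels(), collapse = ", "), call. = FALSE)
  }
  profile <- model_peak_profile(model, label, axis)
  baseline <- model_baseline(model, axis)
  with_local_seed(seed, {
    jitter_peak <- lognormal_jitter(model$amplitude_cv)
    jitter_base <- lognormal_jitter(model$amplitude_cv)
    noise <- if (model$noise_sd > 0) {
      stats::rnorm(length(axis), 0, model$noise_sd)
    } else {
      numeric(length(axis))
    }
    pmax(jitter_base * baseline + jitter_peak * profile + noise, 0)
  })
}

# Unit-mean log-normal factor with coefficient of variation cv.
lognormal_jitter <- function(cv) {
  if (cv <= 0) return(1)
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(1, -sigma^2 / 2, sigma))
}

#' Describe the composition of a synthetic cohort
#'
#' @param cohort_id Cohort name.
#' @param classes Tibble with columns `label`, `n_patients`, and optionally
#'   `cores_min`, `cores_max` (defaults 1 and 1); cores per patient are
#'   drawn uniformly in that range (never outside 1..6).
#' @param acquisitions_per_core Spectra acquired per core (1..4; the
#'   tissue-microarray protocol acquires 4).
#' @param idcp_core_fraction For patients of the `idcp` class, the
#'   probability that each core beyond the first carries the intraductal
#'   lesion; the first core always does. IDC-P cores hold half their
#'   acquisitions as `idcp` and half as `idcp_adj_cancer`; remaining cores
#'   are invasive cancer.
#' @param seed Integer seed governing cohort structure and, through derived
#'   per-spectrum seeds, all intensities.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(cohort_id, classes, acquisitions_per_core = 4,
                          idcp_core_fraction = 1, seed = 1) {
  classes <- tibble::as_tibble(classes)
  stopifnot(all(c("label", "n_patients") %in% names(classes)))
  if (!("cores_min" %in% names(classes))) classes$cores_min <- 1L
  if (!("cores_max" %in% names(classes))) classes$cores_max <- classes$cores_min
  bad <- setdiff(classes$label, tissue_labels())
  if (length(bad) > 0L) {
    stop("Unknown label(s) in design: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(classes$n_patients >= 0),
            all(classes$cores_min >= 1), all(classes$cores_max <= 6),
            all(classes$cores_min <= classes$cores_max),
            acquisitions_per_core >= 1, acquisitions_per_core <= 4,
            idcp_core_fraction >= 0, idcp_core_fraction <= 1)
  structure(list(cohort_id = cohort_id, classes = classes,
                 acquisitions_per_core = as.integer(acquisitions_per_core),
                 idcp_core_fraction = idcp_core_fraction,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a full tissue-microarray cohort
#'
#' Enumerates patients, cores and acquisitions according to the design and
#' draws every spectrum from the generator model. Each spectrum's seed is
#' derived deterministically from the design seed and the spectrum's
#' position in the enumeration, so identical designs reproduce bit-identical
#' cohorts and subsetting a cohort never changes the retained spectra.
#'
#' @param design A [cohort_design()].
#' @param model A [spectrum_model()].
#' @param axis Wavenumber axis from [build_axis()].
#' @return A cohort tibble with `provenance = "synthetic"`.
#' @export
simulate_cohort <- function(design, model = spectrum_model(),
                            axis = build_axis()) {
  stopifnot(inherits(design, "cohort_design"))
  plan <- with_local_seed(design$seed, cohort_plan(design))
  if (nrow(plan) == 0L) {
    return(new_cohort(
      tibble::tibble(cohort_id = character(), patient_id = character(),
                     core_id = character(), acquisition_index = integer(),
                     label = character(), preprocessed = logical(),
                     provenance = character()),
      matrix(numeric(0), nrow = 0, ncol = length(axis)), axis))
  }
  base <- design$seed %% 1000003L
  spectrum_seeds <- (base * 1000003 + seq_len(nrow(plan))) %% 2147483647
  intensity <- matrix(0, nrow(plan), length(axis))
  for (i in seq_len(nrow(plan))) {
    intensity[i, ] <- simulate_spectrum(model, plan$label[i], axis,
                                        seed = spectrum_seeds[i])
  }
  plan$preprocessed <- FALSE
  plan$provenance <- "synthetic"
  new_cohort(plan, intensity, axis)
}

# Deterministic (given RNG state) enumeration of patients/cores/acquisitions.
cohort_plan <- function(design) {
  rows <- list()
  a <- design$acquisitions_per_core
  for (ci in seq_len(nrow(design$classes))) {
    cls <- design$classes[ci, ]
    for (p in seq_len(cls$n_patients)) {
      patient_id <- sprintf("%s_p%03d", cls$label, p)
      n_cores <- if (cls$cores_max > cls$cores_min) {
        sample(seq(cls$cores_min, cls$cores_max), 1L)
      } else {
        cls$cores_min
      }
      for (core in seq_len(n_cores)) {
        core_id <- sprintf("c%d", core)
        if (cls$label == "idcp") {
          is_idcp_core <- core == 1L ||
            stats::runif(1) < design$idcp_core_fraction
          if (is_idcp_core) {
            n_idcp <- ceiling(a / 2)
            labels <- c(rep("idcp", n_idcp), rep("idcp_adj_cancer", a - n_idcp))
            # a core must carry both tissue regions; with a single
            # acquisition that is impossible, so it stays pure cancer
            if (a < 2L) labels <- rep("cancer", a)
          } else {
            labels <- rep("cancer", a)
          }
        } else {
          labels <- rep(cls$label, a)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cohort_id = design$cohort_id, patient_id = patient_id,
          core_id = core_id, acquisition_index = seq_len(a),
          label = labels)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(cohort_id = character(), patient_id = character(),
                          core_id = character(), acquisition_index = integer(),
                          label = character()))
  }
  dplyr::bind_rows(rows)
}
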