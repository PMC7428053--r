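#' Cohort designs emulating a three-institution tissue-microarray study
#'
#' Returns the three default designs: a training cohort (1 core per
#' patient, 4 acquisitions per core) and two independent testing cohorts
#' with 1-3 and 1-6 cores per patient. Patient counts follow the published
#' compositions of the emulated study arms (benign 99/49/68, invasive
#' cancer 272/76/135, IDC-P 15/14/9, HGPIN 64/9/13); lymphocyte counts are
#' a package choice (40/15/20) since per-cohort lymphocyte compositions are
#' not printed in the emulated study's main text.
#'
#' @param seed Integer; each cohort derives its own sub-seed from it.
#' @param scale Multiplier on all patient counts (rounded up), for quick
#'   reduced-size runs; 1 reproduces the printed compositions.
#' @return Named list of three [cohort_design()] objects: `training`,
#'   `test1`, `test2`.
#' @export
study_designs <- function(seed = 1, scale = 1) {
  stopifnot(scale > 0)
  n <- function(k) as.integer(ceiling(k * scale))
  classes <- function(lymph, benign, cancer, idcp, hgpin,
                      cancer_cores = c(1L, 1L), idcp_cores = c(1L, 2L)) {
    tibble::tibble(
      label = c("lymphocyte", "benign", "cancer", "idcp", "hgpin"),
      n_patients = c(n(lymph), n(benign), n(cancer), n(idcp), n(hgpin)),
      cores_min = c(1L, 1L, cancer_cores[1L], idcp_cores[1L], 1L),
      cores_max = c(1L, 1L, cancer_cores[2L], idcp_cores[2L], 1L))
  }
  list(
    training = cohort_design("training", classes(40, 99, 272, 15, 64),
                             seed = seed * 101L + 1L),
    test1 = cohort_design("test1",
                          classes(15, 49, 76, 14, 9,
                                  cancer_cores = c(1L, 3L)),
                          seed = seed * 101L + 2L),
    test2 = cohort_design("test2",
                          classes(20, 68, 135, 9, 13,
                                  cancer_cores = c(1L, 6L)),
                          seed = seed * 101L + 3L))
}

#' Simulate the three study cohorts
#'
#' @param seed Integer master seed.
#' @param model A [spectrum_model()].
#' @param axis Wavenumber axis.
#' @param scale Patient-count multiplier passed to [study_designs()].
#' @param out_dir If given, each cohort is also written with
#'   [save_cohort()] into `out_dir/<cohort_id>/`.
#' @return Named list of three cohort tibbles.
#' @export
simulate_study_cohorts <- function(seed = 1, model = spectrum_model(),
                                   axis = build_axis(), scale = 1,
                                   out_dir = NULL) {
  designs <- study_designs(seed = seed, scale = scale)
  cohorts <- purrr::map(designs, simulate_cohort, model = model, axis = axis)
  if (!is.null(out_dir)) {
    purrr::iwalk(cohorts, function(ch, nm)
      save_cohort(ch, file.path(out_dir, nm)))
  }
  cohorts
}

#' Run the full synthetic study end to end
#'
#' Simulates the three cohorts, removes backgrounds, trains one classifier
#' per requested contrast on the training cohort (grid search, grouped
#' 5-fold cross-validation), freezes each model, tests it on both testing
#' cohorts, and assigns the selected wavenumbers to reference peaks.
#'
#' @param contrasts Character vector of contrast names (see
#'   [contrast_spec()]).
#' @param seed Integer master seed for simulation and fold shuffles.
#' @param grid Hyperparameter grid.
#' @param radius_points Rolling-ball radius (grid points) used for every
#'   cohort.
#' @param model Spectrum generator model.
#' @param scale Patient-count multiplier for reduced-size runs.
#' @param tolerance_cm1 Peak-assignment tolerance.
#' @param cohorts Optional pre-simulated named list (`training`, `test1`,
#'   `test2`) overriding simulation.
#' @return A list of class `raman_study`: `report` (one metrics row per
#'   contrast and cohort), `models`, `assignments`, `seed`.
#' @export
run_study <- function(contrasts = c("benign_vs_cancer", "idcp_vs_cancer",
                                    "hgpin_vs_idcp"),
                      seed = 1, grid = default_grid(), radius_points = 50,
                      model = spectrum_model(), scale = 1,
                      tolerance_cm1 = 8, cohorts = NULL) {
  if (is.null(cohorts)) {
    cohorts <- simulate_study_cohorts(seed = seed, model = model,
                                      scale = scale)
  }
  prep <- purrr::map(cohorts, preprocess_cohort, radius_points = radius_points)

  models <- list(); rows <- list(); assignments <- list()
  for (ct_name in contrasts) {
    ct <- contrast_spec(ct_name)
    fit <- grid_search_train(prep$training, ct, grid = grid, seed = seed)
    models[[ct_name]] <- fit
    s <- fit$cv_report$summary
    rows[[length(rows) + 1L]] <- tibble::tibble(
      contrast = ct_name, cohort = "training", role = "cv",
      row_unit = NA_character_, n = NA_integer_,
      accuracy = s$mean[s$metric == "accuracy"],
      accuracy_sd = s$sd[s$metric == "accuracy"],
      sensitivity = s$mean[s$metric == "sensitivity"],
      specificity = s$mean[s$metric == "specificity"],
      auc = s$mean[s$metric == "auc"],
      threshold = fit$decision_threshold)
    for (nm in c("test1", "test2")) {
      ev <- evaluate_classifier(fit, prep[[nm]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        contrast = ct_name, cohort = nm, role = "test",
        row_unit = ev$metrics$row_unit, n = ev$metrics$n,
        accuracy = ev$metrics$accuracy, accuracy_sd = NA_real_,
        sensitivity = ev$metrics$sensitivity,
        specificity = ev$metrics$specificity,
        auc = ev$metrics$auc, threshold = ev$metrics$threshold)
    }
    assignments[[ct_name]] <- dplyr::mutate(
      assign_peaks(fit$selection, tolerance_cm1 = tolerance_cm1),
      contrast_trained = ct_name, .before = 1L)
  }

  structure(list(report = dplyr::bind_rows(rows),
                 models = models,
                 assignments = dplyr::bind_rows(assignments),
                 seed = seed),
            class = "raman_study")
}

#' @export
print.raman_study <- function(x, ...) {
  cat(sprintf("<raman_study> seed %d, %d contrast(s)\n", x$seed,
              length(x$models)))
  print(x$report)
  invisible(x)
}

#' Write the study report tables to disk
#'
#' Writes `report.tsv` (one row per contrast and cohort) and
#' `assignments.tsv` (peak assignments of the selected features).
#'
#' @param study A `raman_study`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(study$report, file.path(dir, "report.tsv"))
  readr::write_tsv(study$assignments, file.path(dir, "assignments.tsv"))
  invisible(dir)
}

#' Sensitivity of study metrics to the rolling-ball radius
#'
#' Re-runs a contrast across a vector of radii and tabulates the
#' cross-validation metrics, since the background-removal radius is a free
#' parameter of the pipeline.
#'
#' @param cohort Raw (unpreprocessed) training cohort.
#' @param contrast_name Contrast to train.
#' @param radii Radii (grid points) to sweep.
#' @param grid Hyperparameter grid.
#' @param seed Fold seed.
#' @return Tibble with one row per radius: CV accuracy mean/sd and number
#'   of selected features.
#' @export
radius_sensitivity <- function(cohort, contrast_name = "benign_vs_cancer",
                               radii = c(25, 50, 100), grid = default_grid(),
                               seed = 1) {
  purrr::map_dfr(radii, function(r) {
    prep <- preprocess_cohort(cohort, radius_points = r)
    fit <- grid_search_train(prep, contrast_spec(contrast_name), grid = grid,
                             seed = seed)
    s <- fit$cv_report$summary
    tibble::tibble(radius_points = r,
                   cv_accuracy = s$mean[s$metric == "accuracy"],
                   cv_accuracy_sd = s$sd[s$metric == "accuracy"],
                   n_selected = length(fit$selection$selected_indices))
  })
}
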