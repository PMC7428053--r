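test_that("simulate_spectrum reduces to its deterministic parts", {
  ax <- quick_axis()
  silent <- spectrum_model(noise_sd = 0, amplitude_cv = 0,
                           effect_ref_amplitude = 0,
                           fluor_amplitude = 0, substrate_amplitude = 0)
  silent$base_peaks <- silent$base_peaks[0, ]
  silent$effects <- silent$effects[0, ]
  expect_equal(simulate_spectrum(silent, "benign", ax, 1),
               rep(0, length(ax)))

  # one Gaussian line peaks at the grid point nearest its center
  one <- silent
  one$base_peaks <- tibble::tibble(center_cm1 = 1003, amplitude = 7)
  y <- simulate_spectrum(one, "benign", ax, 1)
  expect_identical(which.max(y), which.min(abs(as.numeric(ax) - 1003)))
  expect_equal(max(y), 7 * exp(-(as.numeric(ax)[which.max(y)] - 1003)^2 /
                                 (2 * (12 / 2.3548200450309493)^2)),
               tolerance = 1e-12)

  expect_error(simulate_spectrum(one, "stroma", ax, 1), "label")
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  ax <- quick_axis(); m <- spectrum_model()
  expect_identical(simulate_spectrum(m, "cancer", ax, 42),
                   simulate_spectrum(m, "cancer", ax, 42))
  expect_false(identical(simulate_spectrum(m, "cancer", ax, 42),
                         simulate_spectrum(m, "cancer", ax, 43)))

  d <- cohort_design("d", tibble::tibble(label = c("benign", "idcp"),
                                         n_patients = c(2, 2),
                                         cores_min = 1, cores_max = 3),
                     seed = 9)
  expect_identical(simulate_cohort(d, m, ax), simulate_cohort(d, m, ax))
})

test_that("cohort structure follows the design", {
  ax <- quick_axis(); m <- spectrum_model()
  # printed composition: patients x cores x acquisitions
  ch <- simulate_cohort(
    cohort_design("pc", tibble::tibble(label = "cancer", n_patients = 272)),
    m, ax)
  expect_identical(nrow(ch), 1088L)
  expect_identical(length(unique(ch$patient_id)), 272L)

  # variable cores per patient: recount matches the manifest rows
  d <- cohort_design("v", tibble::tibble(label = "benign", n_patients = 10,
                                         cores_min = 1, cores_max = 6),
                     seed = 4)
  ch <- simulate_cohort(d, m, ax)
  expect_gte(nrow(ch), 40L); expect_lte(nrow(ch), 240L)
  cores <- dplyr::distinct(tibble::as_tibble(ch)[c("patient_id", "core_id")])
  expect_identical(nrow(ch), nrow(cores) * 4L)
  expect_true(all(table(cores$patient_id) <= 6))

  # empty design
  expect_identical(nrow(simulate_cohort(
    cohort_design("e", tibble::tibble(label = "cancer", n_patients = 0)),
    m, ax)), 0L)
})

test_that("IDC-P cores always pair intraductal and adjacent-cancer spectra", {
  ch <- simulate_cohort(
    cohort_design("i", tibble::tibble(label = c("idcp", "cancer"),
                                      n_patients = c(5, 3),
                                      cores_min = 1, cores_max = 3),
                  idcp_core_fraction = 0.5, seed = 2),
    spectrum_model(), quick_axis())
  idcp_cores <- unique(paste(ch$patient_id, ch$core_id)[ch$label == "idcp"])
  adj_cores <- unique(paste(ch$patient_id, ch$core_id)[
    ch$label == "idcp_adj_cancer"])
  expect_gt(length(idcp_cores), 0)
  expect_setequal(idcp_cores, adj_cores)
  # every idcp patient carries at least one intraductal core
  idcp_patients <- unique(ch$patient_id[grepl("^idcp_", ch$patient_id)])
  expect_true(all(idcp_patients %in% ch$patient_id[ch$label == "idcp"]))
})

test_that("class means shift in the tabulated direction at every feature", {
  ax <- build_axis()
  m <- spectrum_model(noise_sd = 0, amplitude_cv = 0)
  axn <- as.numeric(ax)
  profiles <- sapply(c(benign = "benign", cancer = "cancer", idcp = "idcp",
                       idcp_adj_cancer = "idcp_adj_cancer", hgpin = "hgpin"),
                     function(lb) simulate_spectrum(m, lb, ax, 1))
  sides <- list(benign_vs_cancer = c("benign", "cancer"),
                idcp_vs_cancer = c("idcp", "cancer"),
                hgpin_vs_idcp = c("hgpin", "idcp"))
  ref <- default_peak_reference()
  for (i in seq_len(nrow(ref))) {
    up <- ref$increased_in[i]
    down <- setdiff(sides[[ref$contrast[i]]], up)
    for (f in ref$features[[i]]) {
      j <- which.min(abs(axn - f))
      expect_gt(profiles[j, up], profiles[j, down],
                label = sprintf("%s at %g (up=%s)", ref$contrast[i], f, up))
      if (up == "idcp") {
        expect_gt(profiles[j, "idcp_adj_cancer"], profiles[j, down])
      }
    }
  }
})

test_that("spectrum count scales linearly in patients, cores, acquisitions", {
  counts <- sapply(c(1, 2, 4), function(k) {
    nrow(simulate_cohort(
      cohort_design("s", tibble::tibble(label = "benign", n_patients = 3 * k),
                    acquisitions_per_core = 2),
      spectrum_model(), quick_axis()))
  })
  expect_equal(counts, counts[1] * c(1, 2, 4))
})
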