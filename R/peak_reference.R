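#' Reference table of discriminative prostate Raman peaks
#'
#' The packaged table of the most important spectral features driving each
#' of the three tissue contrasts, with their literature-based molecular
#' assignments: 10 features for benign vs. invasive cancer, 11 for IDC-P
#' vs. invasive cancer, and 5 for HGPIN vs. IDC-P. Feature wavenumbers are
#' the axis positions the feature-selection step retained; peak centers are
#' the literature positions of the underlying Raman bands (some are narrow
#' ranges).
#'
#' @param contrast Optional filter: one of `"benign_vs_cancer"`,
#'   `"idcp_vs_cancer"`, `"hgpin_vs_idcp"`.
#' @return A tibble with columns `contrast`, `feature_cm1` (printed form,
#'   slash-separated when one band contributed several selected features),
#'   `features` (list column of numeric wavenumbers), `center_lo_cm1`,
#'   `center_hi_cm1` (equal when the center is a single value),
#'   `increased_in` (tissue tag: `benign`, `cancer`, `idcp`, `hgpin`),
#'   `vibrational_mode`, `molecules`.
#' @examples
#' default_peak_reference("benign_vs_cancer")
#' @export
default_peak_reference <- function(contrast = NULL) {
  ref <- peak_reference_table()
  if (!is.null(contrast)) {
    contrast <- match.arg(contrast,
                          c("benign_vs_cancer", "idcp_vs_cancer",
                            "hgpin_vs_idcp"))
    ref <- ref[ref$contrast == contrast, ]
  }
  ref
}

peak_reference_table <- function() {
  row <- function(contrast, feature_cm1, features, lo, hi, increased_in,
                  mode, molecules) {
    tibble::tibble(contrast = contrast, feature_cm1 = feature_cm1,
                   features = list(features), center_lo_cm1 = lo,
                   center_hi_cm1 = hi, increased_in = increased_in,
                   vibrational_mode = mode, molecules = molecules)
  }
  dplyr::bind_rows(
    # benign epithelium vs invasive cancer
    row("benign_vs_cancer", "720/733", c(720, 733), 719, 726, "benign",
        "Ring breathing mode, C-S", "DNA/RNA (adenine), protein"),
    row("benign_vs_cancer", "828", 828, 827, 828, "benign",
        "O-P-O stretch, ring breathing", "DNA/RNA backbone, protein (tyrosine)"),
    row("benign_vs_cancer", "841", 841, 853, 853, "benign",
        "C-C stretch, ring breathing", "Protein (proline, tyrosine)"),
    row("benign_vs_cancer", "931", 931, 935, 937, "benign",
        "C-C stretch", "Protein (proline, valine, alpha-helix)"),
    row("benign_vs_cancer", "1012/1013", c(1012, 1013), 1000, 1003, "benign",
        "Symmetric ring breathing", "Protein (phenylalanine)"),
    row("benign_vs_cancer", "1035", 1035, 1031, 1032, "benign",
        "C-H stretch", "Protein (phenylalanine)"),
    row("benign_vs_cancer", "1200", 1200, 1206, 1207, "benign",
        "C-C6H5 stretch", "Protein (phenylalanine, tryptophan, tyrosine)"),
    row("benign_vs_cancer", "1329", 1329, 1338, 1338, "benign",
        "Unknown", "DNA/RNA (adenine)"),
    row("benign_vs_cancer", "1431", 1431, 1447, 1450, "cancer",
        "CH2 deformation", "DNA/RNA, protein, lipid"),
    row("benign_vs_cancer", "1470", 1470, 1484, 1484, "cancer",
        "Ring breathing mode", "DNA/RNA (adenine, guanine)"),
    # IDC-P vs invasive cancer
    row("idcp_vs_cancer", "759", 759, 758, 760, "cancer",
        "Symmetric ring breathing", "Protein (tryptophan)"),
    row("idcp_vs_cancer", "834", 834, 827, 831, "idcp",
        "O-P-O stretch, ring breathing", "DNA/RNA backbone, protein (tyrosine)"),
    row("idcp_vs_cancer", "952", 952, 935, 937, "idcp",
        "C-C stretch", "Protein (proline, valine, alpha-helix)"),
    row("idcp_vs_cancer", "996", 996, 1000, 1003, "cancer",
        "Symmetric ring breathing", "Protein (phenylalanine)"),
    row("idcp_vs_cancer", "1004", 1004, 1000, 1003, "idcp",
        "Symmetric ring breathing", "Protein (phenylalanine)"),
    row("idcp_vs_cancer", "1108", 1108, 1090, 1100, "idcp",
        "O-P-O stretch", "Lipid/phospholipid, DNA backbone"),
    row("idcp_vs_cancer", "1172/1183/1184", c(1172, 1183, 1184), 1171, 1171,
        "idcp", "C-H bend", "Protein (tyrosine)"),
    row("idcp_vs_cancer", "1250/1251", c(1250, 1251), 1242, 1250, "idcp",
        "Amide III", "Protein (beta-sheet)"),
    row("idcp_vs_cancer", "1266", 1266, 1263, 1263, "idcp",
        "Amide III", "DNA/RNA (thymine, adenine), protein (alpha-helix)"),
    row("idcp_vs_cancer", "1477", 1477, 1484, 1484, "cancer",
        "Ring breathing mode", "DNA/RNA (adenine, guanine)"),
    row("idcp_vs_cancer", "1638/1649", c(1638, 1649), 1657, 1667, "cancer",
        "C=O stretch, amide I",
        "Protein (alpha-helix), lipid (fatty acid), DNA/RNA (thymine)"),
    # HGPIN vs IDC-P
    row("hgpin_vs_idcp", "720", 720, 725, 726, "hgpin",
        "C-S stretch, CH2 rocking", "DNA/RNA (adenine), protein"),
    row("hgpin_vs_idcp", "1000/1008", c(1000, 1008), 1000, 1003, "idcp",
        "Symmetric ring breathing", "Protein (phenylalanine)"),
    row("hgpin_vs_idcp", "1233/1234", c(1233, 1234), 1242, 1250, "idcp",
        "Amide III", "Protein (beta-sheet)"),
    row("hgpin_vs_idcp", "1346", 1346, 1338, 1338, "hgpin",
        "CH3CH2", "DNA/RNA (adenine), collagen"),
    row("hgpin_vs_idcp", "1696", 1696, 1657, 1667, "hgpin",
        "C=O stretch, amide I",
        "Protein (alpha-helix), lipid (fatty acid), DNA/RNA (thymine)"))
}
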