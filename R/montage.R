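#' Scalp montage and region grouping
#'
#' The 32-electrode montage used throughout the package (BioSemi labels
#' Fp1 ... Cz) together with its grouping into six scalp regions: frontal,
#' central, parietal, occipital, right temporal and left temporal. Electrode
#' region membership drives the band-by-region power table and restricts
#' phase-synchrony counting to cross-region pairs.
#'
#' @return `biosemi32_labels()` returns the 32 channel labels;
#'   `biosemi32_regions()` returns a named character vector mapping each label
#'   to one region.
#' @export
biosemi32_labels <- function() {
  c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
    "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
    "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
    "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz")
}

#' @rdname biosemi32_labels
#' @export
biosemi32_regions <- function() {
  c(Fp1 = "frontal", AF3 = "frontal", F7 = "frontal", F3 = "frontal",
    Fz = "frontal", F4 = "frontal", F8 = "frontal", AF4 = "frontal",
    Fp2 = "frontal",
    FC1 = "central", FC5 = "central", C3 = "central", Cz = "central",
    C4 = "central", FC6 = "central", FC2 = "central",
    CP1 = "parietal", CP5 = "parietal", P3 = "parietal", Pz = "parietal",
    P4 = "parietal", CP6 = "parietal", CP2 = "parietal",
    PO3 = "occipital", O1 = "occipital", Oz = "occipital",
    O2 = "occipital", PO4 = "occipital",
    T7 = "left_temporal", P7 = "left_temporal",
    T8 = "right_temporal", P8 = "right_temporal")
}

#' @rdname biosemi32_labels
#' @export
eeg_regions <- function() {
  c("frontal", "central", "parietal", "occipital",
    "right_temporal", "left_temporal")
}

#' Frequency band definitions
#'
#' Left-closed, right-open intervals in Hz: theta `[4,8)`, alpha `[8,12)`,
#' beta `[12,30)`. Gamma is deliberately absent: scalp gamma is dominated by
#' muscle activity and is excluded from every analysis here.
#'
#' @return named list of `c(lo, hi)` band edges in Hz.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}
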