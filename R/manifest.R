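# The versioned per-cell feature manifest.
#
# The profiling contract is a fixed vector of 85 named measurements per cell,
# spanning five categories: nucleus, cytoskeleton, global cell morphology,
# TGN, and cargo/vesicles. The manifest is code, not data: the names below
# define the column order of every feature matrix the package emits, and the
# count 85 is enforced by test.

FEATURE_MANIFEST_VERSION <- "1.0"

.manifest_def <- list(
  nucleus = c(
    "nuc_area", "nuc_perimeter", "nuc_major_axis", "nuc_minor_axis",
    "nuc_eccentricity", "nuc_solidity", "nuc_compactness",
    "nuc_intensity_mean", "nuc_intensity_sd", "nuc_intensity_q25",
    "nuc_intensity_median", "nuc_intensity_q75", "nuc_intensity_max",
    "nuc_intensity_integrated", "nuc_to_cell_area_fraction"
  ),
  cytoskeleton = c(
    "actin_intensity_mean", "actin_intensity_sd", "actin_intensity_q25",
    "actin_intensity_median", "actin_intensity_q75", "actin_intensity_max",
    "actin_intensity_integrated", "actin_gradient_mean", "actin_gradient_sd",
    "actin_intensity_cv"
  ),
  cell = c(
    "cell_area", "cell_perimeter", "cell_major_axis", "cell_minor_axis",
    "cell_eccentricity", "cell_elongation", "cell_compactness",
    "cell_roughness", "cell_solidity", "cell_extent",
    "cell_equivalent_diameter", "cell_aspect_ratio", "cyto_area",
    "cyto_area_fraction", "nucleus_displacement"
  ),
  tgn = c(
    "tgn_area", "tgn_perimeter", "tgn_length", "tgn_width", "tgn_elongation",
    "tgn_compactness", "tgn_roughness", "tgn_eccentricity", "tgn_solidity",
    "tgn_extent", "tgn_equivalent_diameter", "tgn_area_fraction",
    "tgn_n_fragments", "tgn_intensity_mean", "tgn_intensity_sd",
    "tgn_intensity_q25", "tgn_intensity_median", "tgn_intensity_q75",
    "tgn_intensity_max", "tgn_intensity_integrated", "tgn_intensity_cv",
    "tgn_to_nucleus_distance", "tgn_channel_cell_mean", "tgn_contrast",
    "tgn_nucleus_overlap_fraction"
  ),
  cargo = c(
    "cargo_ratio", "cargo_mean_in_tgn", "cargo_mean_outside_tgn",
    "cargo_sd_in_tgn", "cargo_sd_outside_tgn", "cargo_median_in_tgn",
    "cargo_median_outside_tgn", "cargo_q25_outside_tgn",
    "cargo_q75_outside_tgn", "cargo_max_in_tgn", "cargo_integrated_in_tgn",
    "cargo_integrated_outside_tgn", "cargo_integrated_fraction_in_tgn",
    "cargo_cell_mean", "cargo_cell_sd", "cargo_cv_outside_tgn",
    "cargo_spot_count", "cargo_spot_mean_intensity", "cargo_spot_total_area",
    "cargo_spot_mean_area"
  )
)

#' The per-cell feature manifest
#'
#' Returns the versioned manifest of the 85 morphological and intensity
#' features computed for every segmented cell, in their canonical order.
#' The five categories follow the profiling design: nucleus, cytoskeleton
#' (cell-body marker), global cell morphology, TGN, and cargo channel
#' (compartment intensities plus vesicle-spot statistics outside the TGN).
#'
#' @return a data.frame with columns `feature` (character, 85 unique names)
#'   and `category`, plus attribute `version`.
#' @examples
#' nrow(feature_manifest())  # 85
#' @export
feature_manifest <- function() {
  df <- data.frame(
    feature = unlist(.manifest_def, use.names = FALSE),
    category = rep(names(.manifest_def), lengths(.manifest_def)),
    stringsAsFactors = FALSE
  )
  attr(df, "version") <- FEATURE_MANIFEST_VERSION
  df
}

#' Feature names in manifest order
#' @return character vector of length 85.
#' @export
feature_names <- function() feature_manifest()$feature
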