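# Genotype presets: the stated control distributions of each assay.
#
# Published control summaries report per-well means pooled across all plates
# of a screen (e.g. 1.34 +/- 0.05 SD over n = 1312 wells). A pooled SD mixes
# within-plate well-to-well variation with between-plate offsets; plate QC,
# however, is computed within plates. The generator therefore decomposes each
# pooled SD into a within-plate component `well_sd` and a between-plate
# component `plate_sd` with pooled_sd^2 = well_sd^2 + plate_sd^2. Default
# split: well_sd = pooled_sd / 3, plate_sd = pooled_sd * sqrt(1 - 1/9), which
# keeps the pooled statistics at their printed values while making the
# within-plate separation wide enough that robust Z' >= 0.3 and SSMD >= 3
# hold on every plate (using the pooled SD as a within-plate SD fails the
# robust Z' gate; see the methods vignette).

#' Construct a genotype preset
#'
#' A preset describes the cargo-ratio distribution of one genotype/condition:
#' the population mean ratio, the per-cell SD, the within-plate SD of per-well
#' means, the between-plate SD of plate offsets, and the expected number of
#' quantified cells per well.
#'
#' @param name preset label.
#' @param true_ratio target population mean of the cargo ratio (dimensionless,
#'   > 0).
#' @param cell_sd per-cell SD of the ratio.
#' @param well_sd within-plate SD of per-well mean ratios.
#' @param plate_sd between-plate SD of additive plate offsets.
#' @param mean_cells_per_well expected quantified cells per well (> 0).
#' @return an object of class `genotype_preset`.
#' @export
genotype_preset <- function(name, true_ratio, cell_sd, well_sd,
                            plate_sd = 0, mean_cells_per_well = 100) {
  stopifnot(is.character(name), length(name) == 1,
            true_ratio > 0, cell_sd >= 0, well_sd >= 0, plate_sd >= 0,
            mean_cells_per_well > 0)
  structure(list(name = name, true_ratio = true_ratio, cell_sd = cell_sd,
                 well_sd = well_sd, plate_sd = plate_sd,
                 mean_cells_per_well = mean_cells_per_well),
            class = "genotype_preset")
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat(sprintf(
    "<genotype_preset> %s: ratio %.3g (cell sd %.3g, well sd %.3g, plate sd %.3g), %g cells/well\n",
    x$name, x$true_ratio, x$cell_sd, x$well_sd, x$plate_sd,
    x$mean_cells_per_well))
  invisible(x)
}

#' Build a preset from a printed pooled per-well summary
#'
#' Splits a pooled per-well SD into within-plate and between-plate components
#' (default split 1/3 vs sqrt(8)/3, preserving the pooled value).
#'
#' @param name preset label.
#' @param mean printed pooled mean of per-well means.
#' @param pooled_sd printed pooled SD of per-well means.
#' @param cell_sd per-cell SD of the ratio.
#' @param mean_cells_per_well expected quantified cells per well.
#' @param within_frac fraction of the pooled SD assigned to the within-plate
#'   component (default 1/3).
#' @return a `genotype_preset`.
#' @export
preset_from_pooled <- function(name, mean, pooled_sd, cell_sd,
                               mean_cells_per_well = 100,
                               within_frac = 1 / 3) {
  stopifnot(within_frac > 0, within_frac <= 1)
  genotype_preset(name, mean,
                  cell_sd = cell_sd,
                  well_sd = pooled_sd * within_frac,
                  plate_sd = pooled_sd * sqrt(1 - within_frac^2),
                  mean_cells_per_well = mean_cells_per_well)
}

#' Built-in assay presets
#'
#' Control-pair presets calibrated to the published pooled per-well control
#' summaries of each assay stage. `negative` is the disease genotype (high
#' cargo ratio, e.g. patient LoF/LoF or KO), `positive` the rescuing genotype
#' (carrier or wildtype). The primary-screen pair is oriented disease > control
#' for consistency with every other assay in the series.
#'
#' Per-cell SDs: the fibroblast value (0.10) is chosen so that the per-cell
#' separation of the two genotypes matches the published rank-AUC of 0.96;
#' the other assays scale roughly with their dynamic range.
#'
#' @param name optional preset-pair name; with no argument, all pairs.
#' @return a named list with elements `negative` and `positive` (each a
#'   `genotype_preset`) plus `render_scale` (magnification scale for
#'   [render_params()]: 1 for 20x fibroblast imaging, 1.5 for the
#'   40x-imaged assays), or the named list of all pairs.
#' @export
tgn_presets <- function(name = NULL) {
  all <- list(
    fibroblast_primary = list(
      negative = preset_from_pooled("LoF/LoF fibroblast", 1.34, 0.05,
                                    cell_sd = 0.10, mean_cells_per_well = 90),
      positive = preset_from_pooled("WT/LoF fibroblast", 1.10, 0.02,
                                    cell_sd = 0.10, mean_cells_per_well = 90),
      render_scale = 1
    ),
    fibroblast_secondary = list(
      negative = preset_from_pooled("LoF/LoF fibroblast", 1.40, 0.07,
                                    cell_sd = 0.10, mean_cells_per_well = 90),
      positive = preset_from_pooled("WT/LoF fibroblast", 1.12, 0.02,
                                    cell_sd = 0.10, mean_cells_per_well = 90),
      render_scale = 1
    ),
    shsy5y_atg9a = list(
      negative = preset_from_pooled("AP4B1-KO SH-SY5Y", 1.80, 0.06,
                                    cell_sd = 0.15, mean_cells_per_well = 300),
      positive = preset_from_pooled("AP4B1-WT SH-SY5Y", 1.17, 0.03,
                                    cell_sd = 0.15, mean_cells_per_well = 300),
      render_scale = 1.5
    ),
    shsy5y_daglb = list(
      negative = preset_from_pooled("AP4B1-KO SH-SY5Y (DAGLB)", 1.80, 0.10,
                                    cell_sd = 0.20, mean_cells_per_well = 300),
      positive = preset_from_pooled("AP4B1-WT SH-SY5Y (DAGLB)", 1.36, 0.07,
                                    cell_sd = 0.20, mean_cells_per_well = 300),
      render_scale = 1.5
    ),
    neuron_atg9a = list(
      negative = preset_from_pooled("SPG50 patient neurons", 4.31, 0.40,
                                    cell_sd = 0.50, mean_cells_per_well = 300),
      positive = preset_from_pooled("Carrier control neurons", 1.56, 0.12,
                                    cell_sd = 0.50, mean_cells_per_well = 300),
      render_scale = 1.5
    )
  )
  if (is.null(name)) return(all)
  if (!name %in% names(all))
    stop_tgn("tgn_config_error", "unknown preset pair '%s'", name)
  all[[name]]
}

#' Construct a compound effect
#'
#' The generative counterpart of a dose-response curve: at dose d the
#' effective population ratio is
#' `r_eff = true_ratio - efficacy * (true_ratio - 1) * d^hill / (d^hill + ec50^hill)`,
#' i.e. `efficacy` is the fraction of the disease-minus-unity gap removed at
#' saturating dose. Toxicity (optional) halves the expected cell count at
#' `tox_ec50`; `autofluorescent` compounds add a dose-scaled offset to the
#' cargo channel background.
#'
#' @param compound_id compound label.
#' @param efficacy fraction in 0..1.
#' @param ec50 half-effect dose, uM (> 0).
#' @param hill Hill coefficient (nonzero).
#' @param tox_ec50 dose halving the expected cell count, uM, or `NA` for
#'   no toxicity.
#' @param tox_hill Hill coefficient of the survival curve.
#' @param autofluorescent logical flag.
#' @param af_slope background offset added per uM of dose when
#'   autofluorescent (intensity units per uM).
#' @return an object of class `compound_effect`.
#' @export
compound_effect <- function(compound_id, efficacy = 0, ec50 = 1, hill = 1.5,
                            tox_ec50 = NA_real_, tox_hill = 2,
                            autofluorescent = FALSE, af_slope = 2) {
  stopifnot(efficacy >= 0, efficacy <= 1, ec50 > 0, hill != 0,
            is.na(tox_ec50) || tox_ec50 > 0)
  structure(list(compound_id = compound_id, efficacy = efficacy, ec50 = ec50,
                 hill = hill, tox_ec50 = tox_ec50, tox_hill = tox_hill,
                 autofluorescent = isTRUE(autofluorescent),
                 af_slope = af_slope),
            class = "compound_effect")
}

#' Effective cargo ratio of a compound at a dose
#'
#' @param preset a `genotype_preset` (the treated genotype).
#' @param effect a `compound_effect` or `NULL` (vehicle).
#' @param dose dose in uM (vectorized); ignored when `effect` is `NULL`.
#' @return expected population mean ratio (monotone in dose when
#'   efficacy > 0).
#' @export
effective_ratio <- function(preset, effect = NULL, dose = 0) {
  if (is.null(effect)) return(rep(preset$true_ratio, length(dose)))
  frac <- dose^effect$hill / (dose^effect$hill + effect$ec50^effect$hill)
  frac[dose <= 0] <- 0
  preset$true_ratio - effect$efficacy * (preset$true_ratio - 1) * frac
}

# Expected cell-count survival fraction at a dose (1 when non-toxic).
survival_fraction <- function(effect, dose) {
  if (is.null(effect) || is.na(effect$tox_ec50)) return(rep(1, length(dose)))
  exp(-log(2) * (dose / effect$tox_ec50)^effect$tox_hill)
}
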