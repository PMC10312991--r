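# Tabular synthetic screens: the fast path of the generator.
#
# Per-well measurements are drawn directly from the stated statistical model
# (no image rendering): the per-well mean ratio of a well with genotype
# preset P, compound effect E and dose d is
#   Normal(r_eff(P, E, d) + plate_offset, P$well_sd)
# with plate_offset shared by all wells of a plate (scaled by each preset's
# plate_sd), the cell count is Poisson with toxicity-dependent survival, and
# raw compartment intensities carry a multiplicative per-plate staining
# factor that the ratio cancels (the rationale for using a ratio metric).

BASE_CYTO_INTENSITY <- 100   # arbitrary fluorescence units
BASE_BACKGROUND <- 5
PLATE_INTENSITY_CV <- 0.10   # SD of the log-normal per-plate staining factor
WELL_INTENSITY_CV <- 0.03
BACKGROUND_SD <- 0.5

#' Simulate per-cell cargo ratios for one condition
#'
#' @param preset a `genotype_preset`.
#' @param n number of cells.
#' @param seed integer seed.
#' @param effect optional `compound_effect`.
#' @param dose dose in uM when `effect` is given.
#' @return data.frame with columns `cell_id`, `ratio`.
#' @export
simulate_cells <- function(preset, n, seed = 0, effect = NULL, dose = 0) {
  r <- effective_ratio(preset, effect, dose)
  with_seed(seed, {
    ratio <- stats::rnorm(n, r, preset$cell_sd)
    ratio <- pmax(ratio, 0.05)  # ratios are positive by construction
    data.frame(cell_id = seq_len(n), ratio = ratio)
  })
}

# classify the *planted* ground truth of a compound well from generator
# parameters (no noise): active when the expected clean ratio clears the
# 3-SD activity threshold against the negative-control preset, toxic when
# the expected cell count clears the 2-SD count threshold.
planted_class <- function(effect, dose, neg_preset, active_sd = 3,
                          toxic_sd = 2) {
  if (is.null(effect)) return("inactive")
  if (effect$autofluorescent) return("artifact")
  r_eff <- effective_ratio(neg_preset, effect, dose)
  active <- r_eff <= neg_preset$true_ratio - active_sd * neg_preset$well_sd
  m <- neg_preset$mean_cells_per_well
  sd_count <- sqrt(m)  # Poisson within-plate spread
  toxic <- survival_fraction(effect, dose) * m <= m - toxic_sd * sd_count
  if (active && toxic) "active_toxic"
  else if (active) "active"
  else if (toxic) "toxic"
  else "inactive"
}

#' Simulate a multi-plate well-level screen table
#'
#' Applies the same `layout` to `n_plates` plates. Control wells follow their
#' role's preset; compound wells follow the negative (disease) preset
#' modulated by the compound's effect at its plated dose.
#'
#' @param layout a `plate_layout` from [make_layout()].
#' @param presets list with elements `negative` and `positive`
#'   (`genotype_preset`s), e.g. one entry of [tgn_presets()].
#' @param effects named list of `compound_effect`s covering every compound in
#'   the layout.
#' @param n_plates number of replicate plates.
#' @param seed integer seed.
#' @return data.frame with one row per well and columns `plate`, `well`,
#'   `row`, `col`, `role`, `compound_id`, `dose_um`, `measured_ratio`,
#'   `cell_count`, `background_intensity`, `intensity_tgn`, `intensity_cyto`,
#'   `truth_ratio`, `truth_class`.
#' @export
simulate_well_table <- function(layout, presets, effects = list(),
                                n_plates = 1, seed = 0) {
  stopifnot(inherits(layout, "plate_layout"),
            all(c("negative", "positive") %in% names(presets)))
  cpds <- unique(stats::na.omit(layout$compound_id))
  missing <- setdiff(cpds, names(effects))
  if (length(missing))
    stop_tgn("tgn_config_error", "no compound_effect for: %s",
             paste(utils::head(missing, 5), collapse = ", "))

  lay <- layout[layout$role != "empty", , drop = FALSE]
  n_wells <- nrow(lay)
  neg <- presets$negative; pos <- presets$positive

  # per-well expected clean ratio, survival, af parameters, truth class
  r_eff <- numeric(n_wells); surv <- rep(1, n_wells)
  af_add <- numeric(n_wells); truth <- character(n_wells)
  well_sd <- numeric(n_wells); plate_sd <- numeric(n_wells)
  mean_cells <- numeric(n_wells)
  for (i in seq_len(n_wells)) {
    role <- lay$role[i]
    if (role == "positive_control") {
      p <- pos; eff <- NULL; dose <- 0
      truth[i] <- "positive_control"
    } else {
      p <- neg
      if (role == "compound") {
        eff <- effects[[lay$compound_id[i]]]
        dose <- lay$dose_um[i]
        truth[i] <- planted_class(eff, dose, neg)
      } else {
        eff <- NULL; dose <- 0
        truth[i] <- "negative_control"
      }
    }
    r_eff[i] <- effective_ratio(p, eff, dose)
    surv[i] <- survival_fraction(eff, dose)
    if (!is.null(eff) && eff$autofluorescent) af_add[i] <- eff$af_slope * dose
    well_sd[i] <- p$well_sd; plate_sd[i] <- p$plate_sd
    mean_cells[i] <- p$mean_cells_per_well
  }

  with_seed(seed, {
    out <- vector("list", n_plates)
    for (pl in seq_len(n_plates)) {
      z_plate <- stats::rnorm(1)                      # shared plate shift
      f_plate <- exp(stats::rnorm(1, 0, PLATE_INTENSITY_CV))  # staining factor
      ratio <- stats::rnorm(n_wells, r_eff + z_plate * plate_sd, well_sd)
      ratio <- pmax(ratio, 0.05)
      cyto <- BASE_CYTO_INTENSITY * f_plate *
        (1 + stats::rnorm(n_wells, 0, WELL_INTENSITY_CV))
      # autofluorescence adds to both compartments, biasing the ratio to 1
      tgn <- cyto * ratio + af_add
      cyto_obs <- cyto + af_add
      measured <- tgn / cyto_obs
      count <- stats::rpois(n_wells, mean_cells * surv)
      bg <- pmax(stats::rnorm(n_wells, BASE_BACKGROUND + af_add,
                              BACKGROUND_SD), 0)
      out[[pl]] <- data.frame(
        plate = pl, well = lay$well, row = lay$row, col = lay$col,
        role = lay$role, compound_id = lay$compound_id,
        dose_um = lay$dose_um,
        measured_ratio = measured, cell_count = count,
        background_intensity = bg,
        intensity_tgn = tgn, intensity_cyto = cyto_obs,
        truth_ratio = r_eff, truth_class = truth,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate a replicate titration series for one compound
#'
#' Measurements are drawn around the generative dose-response curve of the
#' compound in the disease (negative-control) background.
#'
#' @param effect a `compound_effect`.
#' @param preset the treated `genotype_preset` (disease background).
#' @param doses increasing dose vector, uM (> 0).
#' @param n_replicates replicates per dose.
#' @param seed integer seed.
#' @param noise_sd per-measurement SD (default: the preset's well SD).
#' @return data.frame of class `dose_series` with columns `compound_id`,
#'   `dose_um`, `replicate`, `ratio`, `cell_count`, `background`; the planted
#'   parameters are kept in attribute `truth`.
#' @export
simulate_dose_series <- function(effect, preset, doses = dose_ladder(),
                                 n_replicates = 2, seed = 0,
                                 noise_sd = NULL) {
  stopifnot(all(doses > 0), n_replicates >= 1)
  noise_sd <- noise_sd %||% preset$well_sd
  r <- effective_ratio(preset, effect, doses)
  surv <- survival_fraction(effect, doses)
  af <- if (effect$autofluorescent) effect$af_slope * doses else numeric(length(doses))
  with_seed(seed, {
    df <- expand.grid(replicate = seq_len(n_replicates), dose_um = doses,
                      KEEP.OUT.ATTRS = FALSE)
    df <- df[order(df$dose_um, df$replicate), c("dose_um", "replicate")]
    idx <- match(df$dose_um, doses)
    ratio <- stats::rnorm(nrow(df), r[idx], noise_sd)
    if (any(af > 0)) {
      cyto <- BASE_CYTO_INTENSITY
      ratio <- (cyto * ratio + af[idx]) / (cyto + af[idx])
    }
    df$compound_id <- effect$compound_id
    df$ratio <- if (noise_sd == 0 && !any(af > 0)) r[idx] else pmax(ratio, 0.05)
    df$cell_count <- stats::rpois(nrow(df), preset$mean_cells_per_well * surv[idx])
    df$background <- pmax(stats::rnorm(nrow(df), BASE_BACKGROUND + af[idx],
                                       BACKGROUND_SD), 0)
    df <- df[, c("compound_id", "dose_um", "replicate", "ratio",
                 "cell_count", "background")]
    rownames(df) <- NULL
    attr(df, "truth") <- list(effect = effect, preset = preset)
    class(df) <- c("dose_series", "data.frame")
    df
  })
}
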