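# End-to-end orchestration: simulate -> (render/segment/measure) -> QC ->
# hits -> dose -> profile, with config, manifests and reproducible seeds.
# Stages communicate only via documented CSV/JSON schemas, so any stage can
# run on externally supplied data in the same formats.

#' Build a run configuration
#'
#' Defaults follow the screening design: 10 uM single-dose primary screen,
#' activity at -3 SD, toxicity at -2 SD, QC gates robust Z' >= 0.3,
#' SSMD >= 3, inter-assay CV <= 10%, driver threshold r > 0.75.
#'
#' @param out_dir run directory for stage outputs.
#' @param preset_pair name of the control-pair preset ([tgn_presets()]).
#' @param format plate format (96 or 384).
#' @param n_plates number of plates to simulate.
#' @param n_controls control wells per role per plate.
#' @param n_compounds number of library compounds.
#' @param frac_active,frac_toxic,frac_artifact planted class fractions.
#' @param screen_dose single screening dose, uM.
#' @param render logical: also render and analyze field images for the first
#'   `render_wells` wells of plate 1.
#' @param render_wells number of wells to render when `render` is TRUE.
#' @param cells_per_field cells per rendered field.
#' @param active_sd,toxic_sd,z_prime_min,ssmd_min,cv_max,driver_r thresholds.
#' @param min_cells minimum valid cells per quantifiable well.
#' @param seed master integer seed; stage seeds are derived from it.
#' @param stages character vector of stages to run.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("tgnrun"),
                       preset_pair = "fibroblast_primary",
                       format = 384, n_plates = 2, n_controls = 16,
                       n_compounds = 320,
                       frac_active = 0.02, frac_toxic = 0.05,
                       frac_artifact = 0.002, screen_dose = 10,
                       render = FALSE, render_wells = 4,
                       cells_per_field = 12,
                       active_sd = 3, toxic_sd = 2, z_prime_min = 0.3,
                       ssmd_min = 3, cv_max = 10, driver_r = 0.75,
                       min_cells = 5, seed = 0,
                       stages = c("simulate", "analyze", "qc", "hits",
                                  "dose", "profile")) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @param cfg a `run_config`.
#' @return `read_run_config` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# planted compound library: strong actives, toxics, artifacts, inert rest
.build_library <- function(cfg) {
  n <- cfg$n_compounds
  ids <- sprintf("CPD%05d", seq_len(n))
  n_act <- round(cfg$frac_active * n)
  n_tox <- round(cfg$frac_toxic * n)
  n_art <- round(cfg$frac_artifact * n)
  effects <- vector("list", n); names(effects) <- ids
  for (i in seq_len(n)) {
    if (i <= n_act) {
      effects[[i]] <- compound_effect(ids[i], efficacy = 1,
                                      ec50 = cfg$screen_dose / 20, hill = 2)
    } else if (i <= n_act + n_tox) {
      effects[[i]] <- compound_effect(ids[i], efficacy = 0,
                                      tox_ec50 = cfg$screen_dose / 2)
    } else if (i <= n_act + n_tox + n_art) {
      effects[[i]] <- compound_effect(ids[i], efficacy = 0,
                                      autofluorescent = TRUE)
    } else {
      effects[[i]] <- compound_effect(ids[i], efficacy = 0)
    }
  }
  effects
}

.write_manifest <- function(cfg, dir, stage, timing) {
  jsonlite::write_json(
    list(stage = stage,
         config_hash = digest::digest(unclass(cfg)),
         seed = cfg$seed,
         package_version = as.character(utils::packageVersion("tgnscreen")),
         elapsed_s = round(timing, 3)),
    file.path(dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA)
}

#' Run the full screening pipeline
#'
#' Executes the configured stages in order, writing every stage output as
#' CSV/JSON under `cfg$out_dir` together with a manifest (config hash, seed,
#' package version, timing). Reruns with the same config are bit-identical
#' for tabular outputs. A stage failure halts with a stage-tagged error;
#' outputs of completed stages are preserved.
#'
#' @param cfg a `run_config`.
#' @return (invisibly) a list with the main in-memory results: `wells`,
#'   `qc`, `calls`, `cascade`, `fits`, `profile`.
#' @export
run_screen_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  run_stage <- function(stage, fun) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(fun(), error = function(e)
      stop_tgn("tgn_stage_error", "[stage %s] %s", stage, conditionMessage(e)))
    .write_manifest(cfg, cfg$out_dir, stage, proc.time()[["elapsed"]] - t0)
    r
  }

  presets <- tgn_presets(cfg$preset_pair)
  effects <- .build_library(cfg)

  res$wells <- run_stage("simulate", function() {
    per_plate <- plate_capacity(cfg$format) - 2L * cfg$n_controls
    assign_rows <- data.frame(
      compound_id = names(effects),
      dose_um = cfg$screen_dose)
    # compounds are split into plate-sized chunks; plates cycle through the
    # chunks, so a library fitting one plate yields replicate plates
    n_chunks <- max(1L, ceiling(length(effects) / per_plate))
    wells <- list()
    for (p in seq_len(cfg$n_plates)) {
      ch <- (p - 1L) %% n_chunks + 1L
      idx <- ((ch - 1L) * per_plate + 1L):min(ch * per_plate, length(effects))
      lay <- make_layout(cfg$format, cfg$n_controls, assign_rows[idx, ])
      w <- simulate_well_table(lay, presets, effects, n_plates = 1,
                               seed = child_seed(cfg$seed, p))
      w$plate <- p
      wells[[p]] <- w
    }
    wells <- do.call(rbind, wells)
    utils::write.csv(wells, file.path(cfg$out_dir, "wells.csv"),
                     row.names = FALSE)
    wells
  })

  res$cells <- run_stage("analyze", function() {
    if (!isTRUE(cfg$render)) return(NULL)
    lay1 <- res$wells[res$wells$plate == 1, ]
    take <- utils::head(order(lay1$role != "negative_control"),
                        cfg$render_wells)
    recs <- list()
    for (i in seq_along(take)) {
      w <- lay1[take[i], ]
      rf <- render_field(presets$negative, cfg$cells_per_field,
                         seed = child_seed(cfg$seed, 1000 + i),
                         well = w$well)
      write_field(rf$field,
                  file.path(cfg$out_dir, sprintf("field_%s.tif", w$well)))
      seg <- segment_field(rf$field)
      cr <- measure_cells(rf$field, seg)
      cr$well <- w$well
      recs[[i]] <- cr
    }
    recs <- do.call(rbind, recs)
    utils::write.csv(recs, file.path(cfg$out_dir, "cells.csv"),
                     row.names = FALSE)
    recs
  })

  res$qc <- run_stage("qc", function() {
    qc <- plate_qc(res$wells, cfg$z_prime_min, cfg$ssmd_min, cfg$cv_max)
    utils::write.csv(qc, file.path(cfg$out_dir, "plate_qc.csv"),
                     row.names = FALSE)
    jsonlite::write_json(gate_plates(qc, cfg$z_prime_min, cfg$ssmd_min,
                                     cfg$cv_max)[c("passed", "failed")],
                         file.path(cfg$out_dir, "plate_qc.json"))
    qc
  })

  run_stage("hits", function() {
    z <- well_zscores(res$wells)
    calls <- classify_compounds(z, active_sd = cfg$active_sd,
                                toxic_sd = cfg$toxic_sd)
    counts <- tally_calls(calls)
    n_in <- nrow(calls)
    casc <- cascade_report(list(cascade_stage(
      "primary", n_in, counts[c("active", "toxic", "active_toxic",
                                "inactive")],
      survivors = counts[["active"]])))
    utils::write.csv(calls, file.path(cfg$out_dir, "compound_calls.csv"),
                     row.names = FALSE)
    utils::write.csv(casc, file.path(cfg$out_dir, "cascade.csv"),
                     row.names = FALSE)
    res$calls <<- calls; res$cascade <<- casc
  })

  res$fits <- run_stage("dose", function() {
    hit_ids <- res$calls$compound_id[res$calls$classification == "active"]
    hit_ids <- utils::head(hit_ids, 8)
    if (!length(hit_ids)) return(NULL)
    fits <- list()
    for (i in seq_along(hit_ids)) {
      ser <- simulate_dose_series(effects[[hit_ids[i]]], presets$negative,
                                  seed = child_seed(cfg$seed, 2000 + i))
      fits[[hit_ids[i]]] <- fit_4pl(ser)
    }
    tab <- ec50_summary(fits)$table
    utils::write.csv(tab, file.path(cfg$out_dir, "dose_fits.csv"),
                     row.names = FALSE)
    fits
  })

  res$profile <- run_stage("profile", function() {
    if (is.null(res$cells)) return(NULL)
    pm <- build_profile_matrix(res$cells[res$cells$valid, ],
                               labels = res$cells$well[res$cells$valid])
    pca <- run_pca(pm, k = 2)
    corr <- pc_feature_correlation(pm, pca, 1, cfg$driver_r)
    utils::write.csv(corr, file.path(cfg$out_dir, "pc1_drivers.csv"),
                     row.names = FALSE)
    list(pm = pm, pca = pca, drivers = corr)
  })

  invisible(res)
}

#' Number of wells in a plate format
#' @param format 96 or 384.
#' @return well count.
#' @export
plate_capacity <- function(format) prod(plate_dims(format))

#' Command-line entry point
#'
#' Subcommands: `simulate`, `analyze`, `qc`, `hits`, `dose`, `profile`,
#' `run-all`. Each runs the pipeline with the corresponding stage toggle;
#' `--config cfg.yaml` supplies a configuration, `--out`/`--seed` override
#' it. Installed alongside the package as `inst/cli/tgnscreen`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status (0 on success), invisibly.
#' @export
tgn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: tgnscreen <simulate|analyze|qc|hits|dose|profile|run-all>",
    " [--config cfg.yaml] [--out DIR] [--seed N]\n")
  if (!length(args)) { cat(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  opt <- list(config = NULL, out = NULL, seed = NULL)
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opt) || i == length(rest)) { cat(usage); return(invisible(1L)) }
    opt[[key]] <- rest[i + 1]; i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else run_config()
  if (!is.null(opt$out)) cfg$out_dir <- opt$out
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  stage_map <- list(
    simulate = "simulate",
    analyze = c("simulate", "analyze"),
    qc = c("simulate", "qc"),
    hits = c("simulate", "qc", "hits"),
    dose = c("simulate", "qc", "hits", "dose"),
    profile = c("simulate", "analyze", "profile"),
    `run-all` = c("simulate", "analyze", "qc", "hits", "dose", "profile"))
  if (!cmd %in% names(stage_map)) { cat(usage); return(invisible(1L)) }
  cfg$stages <- stage_map[[cmd]]
  if (cmd == "profile") cfg$render <- TRUE
  run_screen_pipeline(cfg)
  cat("outputs written to ", cfg$out_dir, "\n", sep = "")
  invisible(0L)
}
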