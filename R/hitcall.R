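# Z-score hit calling against same-plate negative controls and
# triage-cascade bookkeeping.

#' Per-compound z-scores against same-plate negative controls
#'
#' For every compound well, `z = (value - mean_neg) / sd_neg` where the mean
#' and SD come from the negative-control wells of the same plate (ratio and
#' cell count separately). Using same-plate controls avoids bias from
#' inter-plate variability.
#'
#' @param wells data.frame with columns `plate`, `role`, `compound_id`,
#'   `measured_ratio`, `cell_count` (plus any others, carried through).
#' @return data.frame of compound wells with added `z_ratio`, `z_count`.
#' @export
well_zscores <- function(wells) {
  out <- list()
  for (p in sort(unique(wells$plate))) {
    w <- wells[wells$plate == p, , drop = FALSE]
    neg <- w[w$role == "negative_control", , drop = FALSE]
    if (nrow(neg) < 2)
      stop_tgn("tgn_config_error",
               "plate %s has < 2 negative-control wells", p)
    mr <- mean(neg$measured_ratio); sr <- stats::sd(neg$measured_ratio)
    mc <- mean(neg$cell_count); sc <- stats::sd(neg$cell_count)
    if (sr == 0 || sc == 0)
      stop_tgn("tgn_degenerate_controls",
               "plate %s has zero negative-control variance", p)
    cw <- w[w$role == "compound", , drop = FALSE]
    cw$z_ratio <- (cw$measured_ratio - mr) / sr
    cw$z_count <- (cw$cell_count - mc) / sc
    out[[length(out) + 1]] <- cw
  }
  do.call(rbind, out)
}

#' Classify compounds from z-scores
#'
#' Activity: ratio reduced by at least `active_sd` SD (`z_ratio <=
#' -active_sd`, boundary inclusive). Toxicity: cell count reduced by at
#' least `toxic_sd` SD (`z_count <= -toxic_sd`). Classes are mutually
#' exclusive: `active` (active, not toxic), `toxic` (toxic, not active),
#' `active_toxic` (both), `inactive` (neither), `excluded_unquantifiable`
#' (in `exclusions`). Compounds with several wells are classified on their
#' mean z-scores.
#'
#' @param zscores data.frame from [well_zscores()].
#' @param exclusions character vector of pre-excluded compound ids.
#' @param active_sd,toxic_sd thresholds in SD units (positive numbers).
#' @return data.frame: compound_id, z_ratio, z_count, classification.
#' @export
classify_compounds <- function(zscores, exclusions = character(),
                               active_sd = 3, toxic_sd = 2) {
  agg <- stats::aggregate(cbind(z_ratio, z_count) ~ compound_id,
                          data = zscores, FUN = mean)
  act <- agg$z_ratio <= -active_sd
  tox <- agg$z_count <= -toxic_sd
  cls <- ifelse(act & tox, "active_toxic",
                ifelse(act, "active", ifelse(tox, "toxic", "inactive")))
  cls[agg$compound_id %in% exclusions] <- "excluded_unquantifiable"
  data.frame(compound_id = agg$compound_id, z_ratio = agg$z_ratio,
             z_count = agg$z_count, classification = cls,
             stringsAsFactors = FALSE)
}

#' Define one triage-cascade stage
#'
#' Groups may overlap (screen reports routinely count, e.g., all
#' toxicity-affected compounds in one group and all actives in another, with
#' active+toxic compounds in both), so only each individual count is checked
#' against the stage input.
#'
#' @param name stage label.
#' @param input number of compounds entering the stage (the percentage
#'   denominator).
#' @param counts named integer vector of per-group counts at this stage.
#' @param survivors number of compounds forwarded to the next stage.
#' @return a `cascade_stage` list.
#' @export
cascade_stage <- function(name, input, counts, survivors) {
  stopifnot(is.numeric(input), input >= 0, all(counts >= 0),
            survivors >= 0)
  if (any(counts > input) || survivors > input)
    stop_tgn("tgn_consistency_error",
             "stage '%s': a group count exceeds the input (%d)",
             name, input)
  structure(list(name = name, input = input, counts = counts,
                 survivors = survivors), class = "cascade_stage")
}

#' Triage-cascade report
#'
#' Checks that each stage's input equals the previous stage's survivors and
#' tabulates per-class counts with percentages of the stage input, rounded
#' half-up to one decimal. Percentages are always derived from the stored
#' counts.
#'
#' @param stages list of [cascade_stage()] objects, in order.
#' @return data.frame of class `cascade_report`: stage, group, count,
#'   percent.
#' @export
cascade_report <- function(stages) {
  for (i in seq_along(stages)) {
    if (i > 1 && stages[[i]]$input != stages[[i - 1]]$survivors)
      stop_tgn("tgn_consistency_error",
               "stage '%s' input (%d) != previous survivors (%d)",
               stages[[i]]$name, stages[[i]]$input,
               stages[[i - 1]]$survivors)
  }
  rows <- lapply(stages, function(s) {
    data.frame(stage = s$name,
               group = c(names(s$counts), "survivors"),
               count = c(unname(s$counts), s$survivors),
               percent = round_half_up(
                 100 * c(unname(s$counts), s$survivors) / s$input, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cascade_report", "data.frame")
  out
}

#' Tally classification calls into cascade counts
#'
#' @param calls data.frame from [classify_compounds()].
#' @return named integer vector of counts per classification.
#' @export
tally_calls <- function(calls) {
  lv <- c("inactive", "active", "toxic", "active_toxic",
          "excluded_unquantifiable")
  tab <- table(factor(calls$classification, levels = lv))
  stats::setNames(as.integer(tab), lv)
}
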