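# Stable CSV/TIFF exchange formats for stage outputs.

#' Write / read per-cell records as CSV
#'
#' Column order is `cell_id`, `valid`, then the 85 manifest features; the
#' manifest version travels in a header comment.
#'
#' @param cells data.frame from [measure_cells()].
#' @param path CSV path.
#' @return `read_cell_records` returns the records with the
#'   `manifest_version` attribute restored.
#' @export
write_cell_records <- function(cells, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# manifest_version=%s",
                     attr(cells, "manifest_version") %||%
                       FEATURE_MANIFEST_VERSION), con)
  utils::write.csv(cells, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_records
#' @export
read_cell_records <- function(path) {
  first <- readLines(path, n = 1)
  version <- sub("^# manifest_version=", "", first)
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "manifest_version") <- version
  df
}

#' Write / read a well-level table as CSV
#'
#' @param wells well table (e.g. from [simulate_well_table()] or built from
#'   [summarize_well()] rows).
#' @param path CSV path.
#' @return `read_well_table` returns the data.frame.
#' @export
write_well_table <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_well_table
#' @export
read_well_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write rendered-field ground truth
#'
#' The per-cell truth table goes to `<stem>_cells.csv`; the nucleus, cell
#' and TGN label maps go to `<stem>_labels.tif` (3-page 16-bit TIFF).
#'
#' @param truth the `truth` element returned by [render_field()].
#' @param stem output path stem (no extension).
#' @return invisible character vector of the files written.
#' @export
write_ground_truth <- function(truth, stem) {
  csv <- paste0(stem, "_cells.csv")
  tif <- paste0(stem, "_labels.tif")
  utils::write.csv(truth$cells, csv, row.names = FALSE)
  write_tiff(truth$labels[c("nucleus", "cell", "tgn")], tif)
  invisible(c(csv, tif))
}

#' Save segmentation label maps as a 16-bit TIFF
#'
#' Pages: nucleus, cell, TGN label maps.
#'
#' @param seg a `segmentation_result`.
#' @param path TIFF path.
#' @export
write_segmentation <- function(seg, path) {
  write_tiff(list(nucleus = seg$nucleus_labels, cell = seg$cell_labels,
                  tgn = seg$tgn_labels), path)
  invisible(path)
}
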