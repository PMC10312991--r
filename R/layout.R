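# Plate layouts: well/role maps for 96- and 384-well plates.

plate_dims <- function(format) {
  format <- as.integer(format)
  if (format == 96L) c(rows = 8L, cols = 12L)
  else if (format == 384L) c(rows = 16L, cols = 24L)
  else stop_tgn("tgn_capacity_error", "unsupported plate format %d", format)
}

well_names <- function(format) {
  d <- plate_dims(format)
  # row-major: A01, A02, ..., then B01 ...
  paste0(rep(LETTERS[seq_len(d["rows"])], each = d["cols"]),
         sprintf("%02d", rep(seq_len(d["cols"]), d["rows"])))
}

#' Standard two-fold titration dose ladder
#'
#' Doses are generated by repeated halving from the top dose and rounded half
#' up to two decimals, reproducing the conventional printed series
#' 0.04, 0.08, 0.16, 0.31, 0.63, 1.25, 2.5, 5, 10, 20, 40 uM for an 11-point
#' range 0.04-40 uM.
#'
#' @param low lowest dose, uM.
#' @param high highest dose, uM.
#' @param n number of points.
#' @return increasing numeric vector of length `n`.
#' @examples
#' dose_ladder(0.04, 40, 11)
#' @export
dose_ladder <- function(low = 0.04, high = 40, n = 11) {
  stopifnot(low > 0, high > low, n >= 2)
  d <- round_half_up(high / 2^((n - 1):0), 2)
  if (abs(d[1] - low) > 0.25 * low)
    warning("two-fold ladder from `high` does not land on `low`; ",
            "ladder starts at ", d[1])
  d
}

#' Build a deterministic plate layout
#'
#' Controls occupy the outermost two columns on each side of the plate
#' (columns 1, 2 and ncol-1, ncol), alternating negative/positive down the
#' rows; compound wells fill the remaining wells in row-major order.
#'
#' @param format 96 or 384.
#' @param n_control_wells_per_role number of wells for each control role.
#' @param compound_assignments data.frame with columns `compound_id` and
#'   `dose_um` (one row per compound well), or `NULL` for a control-only
#'   plate.
#' @return a data.frame of class `plate_layout` with columns `well`, `row`,
#'   `col`, `role` (negative_control / positive_control / compound / empty),
#'   `compound_id`, `dose_um`.
#' @examples
#' lay <- make_layout(96, 8, data.frame(compound_id = paste0("cpd", 1:10)[
#'   rep(1:10, each = 8)], dose_um = rep(dose_ladder(0.31, 40, 8), 10)))
#' table(lay$role)
#' @export
make_layout <- function(format, n_control_wells_per_role,
                        compound_assignments = NULL) {
  d <- plate_dims(format)
  nr <- d[["rows"]]; nc <- d[["cols"]]
  wells <- well_names(format)
  lay <- data.frame(
    well = wells,
    row = rep(seq_len(nr), each = nc),
    col = rep(seq_len(nc), nr),
    role = "empty",
    compound_id = NA_character_,
    dose_um = NA_real_,
    stringsAsFactors = FALSE
  )
  ctrl_cols <- c(1L, 2L, nc - 1L, nc)
  ctrl_idx <- which(lay$col %in% ctrl_cols)
  # order control slots column-by-column so both roles span all rows
  ctrl_idx <- ctrl_idx[order(match(lay$col[ctrl_idx], ctrl_cols),
                             lay$row[ctrl_idx])]
  n_ctrl <- n_control_wells_per_role
  if (2L * n_ctrl > length(ctrl_idx))
    stop_tgn("tgn_capacity_error",
             "%d control wells per role exceed the %d control slots",
             n_ctrl, length(ctrl_idx))
  roles <- rep(c("negative_control", "positive_control"),
               length.out = 2L * n_ctrl)
  lay$role[ctrl_idx[seq_len(2L * n_ctrl)]] <- roles

  if (!is.null(compound_assignments)) {
    ca <- as.data.frame(compound_assignments)
    stopifnot("compound_id" %in% names(ca))
    if (is.null(ca$dose_um)) ca$dose_um <- 10
    if (any(!is.finite(ca$dose_um)) || any(ca$dose_um <= 0))
      stop_tgn("tgn_config_error", "compound doses must be positive")
    free <- which(lay$role == "empty")
    if (nrow(ca) > length(free))
      stop_tgn("tgn_capacity_error",
               "%d compound wells requested but only %d free wells",
               nrow(ca), length(free))
    take <- free[seq_len(nrow(ca))]
    lay$role[take] <- "compound"
    lay$compound_id[take] <- as.character(ca$compound_id)
    lay$dose_um[take] <- ca$dose_um
  }
  class(lay) <- c("plate_layout", "data.frame")
  attr(lay, "format") <- as.integer(format)
  lay
}

#' Write / read a plate layout as CSV
#'
#' Columns: well, role, compound_id, dose_um.
#' @param layout a `plate_layout`.
#' @param path file path.
#' @return `read_layout` returns a `plate_layout`.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(layout[, c("well", "role", "compound_id", "dose_um")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_layout
#' @param format plate format of the file being read (96 or 384).
#' @export
read_layout <- function(path, format = 384) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(well = "character",
                                       role = "character",
                                       compound_id = "character"))
  df$compound_id[df$compound_id == ""] <- NA_character_
  wl <- well_names(format)
  m <- match(df$well, wl)
  if (anyNA(m))
    stop_tgn("tgn_config_error", "layout wells do not match a %d-well plate",
             format)
  d <- plate_dims(format)
  df$row <- (m - 1L) %/% d[["cols"]] + 1L
  df$col <- (m - 1L) %% d[["cols"]] + 1L
  df <- df[, c("well", "row", "col", "role", "compound_id", "dose_um")]
  class(df) <- c("plate_layout", "data.frame")
  attr(df, "format") <- as.integer(format)
  df
}
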