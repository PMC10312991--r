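# Segmentation of fields into cells and compartments.
#
# Mask hierarchy: nuclei from the nucleus channel (global Otsu threshold,
# hole filling, distance-transform watershed to split touching nuclei), cell
# bodies from the cell-body channel seeded by nuclei (a cell exists only
# where a nucleus lies inside a cell-body-positive region), the TGN as the
# thresholded TGN channel intersected with each cell, and the cytoplasm as
# cell minus TGN. Cells touching the image border are dropped.

#' Segmentation parameters
#'
#' @param blur_sigma pre-threshold Gaussian smoothing SD (px).
#' @param min_nucleus_area smallest accepted nucleus (px^2).
#' @param nucleus_split_radius minimum interior radius for watershed markers.
#' @param min_cell_area smallest accepted cell (px^2).
#' @return parameter list.
#' @export
segment_params <- function(blur_sigma = 1, min_nucleus_area = 30,
                           nucleus_split_radius = 3, min_cell_area = 120) {
  as.list(environment())
}

.threshold_mask <- function(ch, sigma) {
  sm <- gaussian_blur(ch, sigma)
  thr <- otsu_threshold(sm)
  if (is.na(thr)) return(NULL)
  sm > thr
}

#' Segment a field into nuclei, cells and TGN
#'
#' @param field a `field_image`.
#' @param params from [segment_params()].
#' @return an object of class `segmentation_result`: list with integer label
#'   matrices `nucleus_labels`, `cell_labels`, `tgn_labels` (same label =
#'   same cell), the parameters used, and `blank` flag (TRUE when a channel
#'   carried no signal; the result is then empty, with a warning).
#' @export
segment_field <- function(field, params = segment_params()) {
  stopifnot(inherits(field, "field_image"))
  dims <- dim(field$channels[[1]])
  empty <- function(blank) {
    z <- matrix(0L, dims[1], dims[2])
    structure(list(nucleus_labels = z, cell_labels = z, tgn_labels = z,
                   params = params, blank = blank),
              class = "segmentation_result")
  }
  nuc_mask <- .threshold_mask(field$channels$nucleus, params$blur_sigma)
  cell_mask <- .threshold_mask(field$channels$cellbody, params$blur_sigma)
  if (is.null(nuc_mask) || is.null(cell_mask)) {
    warning("blank nucleus or cell-body channel; returning empty segmentation")
    return(empty(TRUE))
  }
  nuc_mask <- fill_holes(nuc_mask)
  nuc_lab <- watershed_split(nuc_mask, min_radius = params$nucleus_split_radius)
  sizes <- tabulate(nuc_lab[nuc_lab > 0])
  drop <- which(sizes < params$min_nucleus_area)
  if (length(drop)) nuc_lab[nuc_lab %in% drop] <- 0L
  if (!any(nuc_lab > 0)) {
    warning("no nuclei found; returning empty segmentation")
    return(empty(FALSE))
  }
  cell_mask <- fill_holes(cell_mask)
  pri <- gaussian_blur(field$channels$cellbody, params$blur_sigma)
  cell_lab <- seeded_grow(nuc_lab, cell_mask | nuc_lab > 0, priority = pri)

  # nuclei must sit inside a cell-body-positive region: a nucleus whose cell
  # is (almost) nothing beyond the nucleus itself is not a cell
  keep <- sort(unique(cell_lab[cell_lab > 0]))
  cell_sizes <- tabulate(cell_lab, nbins = max(cell_lab))
  nuc_sizes <- tabulate(nuc_lab, nbins = max(cell_lab))
  bad <- keep[cell_sizes[keep] < pmax(params$min_cell_area,
                                      1.2 * nuc_sizes[keep])]
  # drop cells touching the image border
  border <- unique(c(cell_lab[1, ], cell_lab[nrow(cell_lab), ],
                     cell_lab[, 1], cell_lab[, ncol(cell_lab)]))
  bad <- union(bad, border[border > 0])
  if (length(bad)) {
    cell_lab[cell_lab %in% bad] <- 0L
    nuc_lab[nuc_lab %in% bad] <- 0L
  }
  # TGN mask: half-level threshold between the in-cell floor and the TGN
  # plateau, computed over in-cell pixels only. For a PSF-blurred step edge
  # the half-level contour passes through the true structure boundary, so
  # this keeps the mask tight instead of including the blur skirt (which a
  # global Otsu would, diluting the in-TGN cargo mean).
  tgn_lab <- matrix(0L, dims[1], dims[2])
  if (any(cell_lab > 0)) {
    sm <- gaussian_blur(field$channels$tgn, params$blur_sigma)
    v <- sm[cell_lab > 0]
    t1 <- otsu_threshold(v)
    if (!is.na(t1) && any(v > t1)) {
      thr <- (stats::median(v[v <= t1]) + stats::median(v[v > t1])) / 2
      sel <- sm > thr & cell_lab > 0
      tgn_lab[sel] <- cell_lab[sel]
    } else {
      warning("blank TGN channel; TGN masks empty")
    }
  }
  structure(list(nucleus_labels = nuc_lab, cell_labels = cell_lab,
                 tgn_labels = tgn_lab, params = params, blank = FALSE),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d cells%s\n",
              length(setdiff(unique(as.vector(x$cell_labels)), 0L)),
              if (x$blank) " (blank input)" else ""))
  invisible(x)
}

#' Shape descriptors of a binary region
#'
#' Area in px^2, Crofton perimeter, best-fit-ellipse full axis lengths
#' (`length` >= `width`), elongation = width/length, compactness =
#' perimeter^2 / (4 pi area), and roughness = its reciprocal (the classic
#' shape factor 4 pi area / perimeter^2, equal to 1 for a disk). Multi-part
#' regions are measured on the union: summed area and perimeter, ellipse fit
#' on all pixels.
#'
#' @param mask logical matrix (nonempty).
#' @return list with area, perimeter, length, width, elongation, compactness,
#'   roughness, eccentricity.
#' @export
tgn_shape <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop_tgn("tgn_shape_error", "shape of an empty region is undefined")
  area <- nrow(idx)
  per <- perimeter_crofton(mask)
  ax <- ellipse_axes(idx[, 1], idx[, 2])
  list(area = area, perimeter = per,
       length = ax$length, width = ax$width,
       elongation = ax$width / ax$length,
       compactness = per^2 / (4 * pi * area),
       roughness = 4 * pi * area / per^2,
       eccentricity = ax$eccentricity)
}

#' Measure all cells of a segmented field
#'
#' Per cell: cargo compartment means over TGN pixels and over
#' cell-minus-TGN (cytoplasm) pixels, their ratio, TGN shape metrics, and
#' the full 85-feature manifest vector. Cells with an empty TGN or empty
#' cytoplasm mask are flagged invalid (features `NA`) and are excluded from
#' well means.
#'
#' @param field a `field_image`.
#' @param seg matching `segmentation_result`.
#' @return data.frame with columns `cell_id`, `valid`, and the 85 manifest
#'   features; attribute `manifest_version`.
#' @export
measure_cells <- function(field, seg) {
  ids <- setdiff(sort(unique(as.vector(seg$cell_labels))), 0L)
  feats <- feature_names()
  out <- as.data.frame(matrix(NA_real_, length(ids), length(feats),
                              dimnames = list(NULL, feats)))
  valid <- logical(length(ids))
  if (length(ids)) {
    grad <- abs(field$channels$cellbody -
                  shift_mat(field$channels$cellbody, 0, 1,
                            field$channels$cellbody[1, 1])) +
            abs(field$channels$cellbody -
                  shift_mat(field$channels$cellbody, 1, 0,
                            field$channels$cellbody[1, 1]))
    for (k in seq_along(ids)) {
      row <- cell_features(field, seg, ids[k], grad)
      if (!is.null(row)) { out[k, ] <- row; valid[k] <- TRUE }
    }
  }
  res <- cbind(data.frame(cell_id = ids, valid = valid), out)
  attr(res, "manifest_version") <- FEATURE_MANIFEST_VERSION
  res
}

#' Summarize one well from its cell records
#'
#' The well mean ratio is the unweighted mean of valid per-cell ratios
#' (per-cell then per-well aggregation; no per-field intermediate). Wells
#' with fewer than `min_cells` valid cells are flagged excluded.
#'
#' @param cells data.frame from [measure_cells()] (rows of one well; may be
#'   a rbind over the well's fields).
#' @param layout_entry optional single-row layout data.frame (well, role,
#'   compound_id, dose_um).
#' @param background cargo-channel background intensity outside all cells.
#' @param min_cells minimum valid cells for a quantifiable well.
#' @return single-row data.frame: well, role, compound_id, dose_um,
#'   mean_ratio, cell_count, background_intensity, excluded, plus the mean
#'   feature vector (85 columns).
#' @export
summarize_well <- function(cells, layout_entry = NULL, background = NA_real_,
                           min_cells = 20) {
  ok <- cells[cells$valid %in% TRUE, , drop = FALSE]
  n <- nrow(ok)
  feats <- feature_names()
  fmeans <- if (n > 0) colMeans(ok[, feats, drop = FALSE]) else
    stats::setNames(rep(NA_real_, length(feats)), feats)
  data.frame(
    well = layout_entry$well %||% NA_character_,
    role = layout_entry$role %||% NA_character_,
    compound_id = layout_entry$compound_id %||% NA_character_,
    dose_um = layout_entry$dose_um %||% NA_real_,
    mean_ratio = if (n >= 1) mean(ok$cargo_ratio) else NA_real_,
    cell_count = n,
    background_intensity = background,
    excluded = n < min_cells,
    t(fmeans),
    stringsAsFactors = FALSE
  )
}

#' Cargo-channel background of a field
#'
#' Mean cargo intensity over pixels outside all cells.
#' @param field a `field_image`.
#' @param seg matching `segmentation_result`.
#' @return scalar intensity.
#' @export
field_background <- function(field, seg) {
  mean(field$channels$cargo[seg$cell_labels == 0L])
}
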