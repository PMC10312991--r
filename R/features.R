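# Per-cell computation of the 85-feature manifest.

# quantile/sd helpers that stay defined for 1-pixel regions
.q <- function(x, p) as.numeric(stats::quantile(x, p, names = FALSE, type = 7))
.sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0

# extract the bounding-box submask of one label (padded by 1 px)
.submask <- function(lab, id) {
  idx <- which(lab == id, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - 1L); r1 <- min(nrow(lab), max(idx[, 1]) + 1L)
  c0 <- max(1L, min(idx[, 2]) - 1L); c1 <- min(ncol(lab), max(idx[, 2]) + 1L)
  list(mask = lab[r0:r1, c0:c1, drop = FALSE] == id,
       rows = idx[, 1], cols = idx[, 2])
}

.region_shape <- function(sub) {
  s <- tgn_shape(sub$mask)
  bbox <- prod(dim(sub$mask) - c(2L, 2L))  # unpadded bounding box
  s$solidity <- s$area / convex_area(sub$rows, sub$cols)
  s$extent <- s$area / max(bbox, 1)
  s$equivalent_diameter <- 2 * sqrt(s$area / pi)
  s
}

# Compute the 85 manifest features for one cell; NULL when the cell has an
# empty TGN or empty cytoplasm compartment (record flagged invalid upstream).
cell_features <- function(field, seg, id, grad) {
  cellpix <- seg$cell_labels == id
  tgnpix <- seg$tgn_labels == id
  cytopix <- cellpix & !tgnpix
  nucpix <- seg$nucleus_labels == id
  if (!any(tgnpix) || !any(cytopix) || !any(nucpix)) return(NULL)

  nuc_ch <- field$channels$nucleus; act_ch <- field$channels$cellbody
  tgn_ch <- field$channels$tgn; car_ch <- field$channels$cargo

  cell_sub <- .submask(seg$cell_labels, id)
  nuc_sub <- .submask(seg$nucleus_labels, id)
  tgn_sub <- .submask(seg$tgn_labels, id)
  cs <- .region_shape(cell_sub)
  ns <- .region_shape(nuc_sub)
  ts <- .region_shape(tgn_sub)

  nv <- nuc_ch[nucpix]; av <- act_ch[cellpix]
  tv <- tgn_ch[tgnpix]; cv_in <- car_ch[tgnpix]; cv_out <- car_ch[cytopix]
  cv_cell <- car_ch[cellpix]

  cell_cen <- c(mean(cell_sub$rows), mean(cell_sub$cols))
  nuc_cen <- c(mean(nuc_sub$rows), mean(nuc_sub$cols))
  tgn_cen <- c(mean(tgn_sub$rows), mean(tgn_sub$cols))

  # cargo vesicle spots: bright cytoplasmic puncta >= 2 px
  thr <- mean(cv_out) + 2 * .sd0(cv_out)
  spot_mask_full <- cytopix & car_ch > thr
  spots <- .submask(seg$cell_labels, id)  # reuse bbox frame
  sm <- matrix(FALSE, nrow(spots$mask), ncol(spots$mask))
  r0 <- min(spots$rows) - 1L; c0 <- min(spots$cols) - 1L
  sel <- which(spot_mask_full, arr.ind = TRUE)
  if (nrow(sel)) {
    rr <- sel[, 1] - r0 + 1L; cc <- sel[, 2] - c0 + 1L
    keep <- rr >= 1 & rr <= nrow(sm) & cc >= 1 & cc <= ncol(sm)
    sm[cbind(rr[keep], cc[keep])] <- TRUE
  }
  spot_lab <- label_components(sm, connectivity = 8)
  spot_sizes <- tabulate(spot_lab[spot_lab > 0])
  spot_sizes <- spot_sizes[spot_sizes >= 2]
  spot_px <- car_ch[spot_mask_full]

  mean_in <- mean(cv_in); mean_out <- mean(cv_out)
  c(
    # nucleus
    nuc_area = ns$area, nuc_perimeter = ns$perimeter,
    nuc_major_axis = ns$length, nuc_minor_axis = ns$width,
    nuc_eccentricity = ns$eccentricity, nuc_solidity = ns$solidity,
    nuc_compactness = ns$compactness,
    nuc_intensity_mean = mean(nv), nuc_intensity_sd = .sd0(nv),
    nuc_intensity_q25 = .q(nv, 0.25), nuc_intensity_median = .q(nv, 0.5),
    nuc_intensity_q75 = .q(nv, 0.75), nuc_intensity_max = max(nv),
    nuc_intensity_integrated = sum(nv),
    nuc_to_cell_area_fraction = ns$area / cs$area,
    # cytoskeleton
    actin_intensity_mean = mean(av), actin_intensity_sd = .sd0(av),
    actin_intensity_q25 = .q(av, 0.25), actin_intensity_median = .q(av, 0.5),
    actin_intensity_q75 = .q(av, 0.75), actin_intensity_max = max(av),
    actin_intensity_integrated = sum(av),
    actin_gradient_mean = mean(grad[cellpix]),
    actin_gradient_sd = .sd0(grad[cellpix]),
    actin_intensity_cv = .sd0(av) / mean(av),
    # cell morphology
    cell_area = cs$area, cell_perimeter = cs$perimeter,
    cell_major_axis = cs$length, cell_minor_axis = cs$width,
    cell_eccentricity = cs$eccentricity, cell_elongation = cs$elongation,
    cell_compactness = cs$compactness, cell_roughness = cs$roughness,
    cell_solidity = cs$solidity, cell_extent = cs$extent,
    cell_equivalent_diameter = cs$equivalent_diameter,
    cell_aspect_ratio = cs$length / cs$width,
    cyto_area = sum(cytopix), cyto_area_fraction = sum(cytopix) / cs$area,
    nucleus_displacement = sqrt(sum((cell_cen - nuc_cen)^2)),
    # TGN
    tgn_area = ts$area, tgn_perimeter = ts$perimeter,
    tgn_length = ts$length, tgn_width = ts$width,
    tgn_elongation = ts$elongation, tgn_compactness = ts$compactness,
    tgn_roughness = ts$roughness, tgn_eccentricity = ts$eccentricity,
    tgn_solidity = ts$solidity, tgn_extent = ts$extent,
    tgn_equivalent_diameter = ts$equivalent_diameter,
    tgn_area_fraction = ts$area / cs$area,
    tgn_n_fragments = max(label_components(tgn_sub$mask, 8)),
    tgn_intensity_mean = mean(tv), tgn_intensity_sd = .sd0(tv),
    tgn_intensity_q25 = .q(tv, 0.25), tgn_intensity_median = .q(tv, 0.5),
    tgn_intensity_q75 = .q(tv, 0.75), tgn_intensity_max = max(tv),
    tgn_intensity_integrated = sum(tv),
    tgn_intensity_cv = .sd0(tv) / mean(tv),
    tgn_to_nucleus_distance = sqrt(sum((tgn_cen - nuc_cen)^2)),
    tgn_channel_cell_mean = mean(tgn_ch[cellpix]),
    tgn_contrast = mean(tv) / mean(tgn_ch[cytopix]),
    tgn_nucleus_overlap_fraction = sum(tgnpix & nucpix) / ts$area,
    # cargo
    cargo_ratio = mean_in / mean_out,
    cargo_mean_in_tgn = mean_in, cargo_mean_outside_tgn = mean_out,
    cargo_sd_in_tgn = .sd0(cv_in), cargo_sd_outside_tgn = .sd0(cv_out),
    cargo_median_in_tgn = .q(cv_in, 0.5),
    cargo_median_outside_tgn = .q(cv_out, 0.5),
    cargo_q25_outside_tgn = .q(cv_out, 0.25),
    cargo_q75_outside_tgn = .q(cv_out, 0.75),
    cargo_max_in_tgn = max(cv_in),
    cargo_integrated_in_tgn = sum(cv_in),
    cargo_integrated_outside_tgn = sum(cv_out),
    cargo_integrated_fraction_in_tgn = sum(cv_in) / sum(cv_cell),
    cargo_cell_mean = mean(cv_cell), cargo_cell_sd = .sd0(cv_cell),
    cargo_cv_outside_tgn = .sd0(cv_out) / mean(cv_out),
    cargo_spot_count = length(spot_sizes),
    cargo_spot_mean_intensity = if (length(spot_px)) mean(spot_px) else 0,
    cargo_spot_total_area = sum(spot_sizes),
    cargo_spot_mean_area = if (length(spot_sizes)) mean(spot_sizes) else 0
  )
}
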