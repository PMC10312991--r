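# Rendering synthetic multichannel fields with ground truth.
#
# Cells are non-overlapping ellipses with an interior nucleus ellipse and a
# perinuclear TGN crescent occupying ~5-15% of the cell area. Channel
# intensities are expected photon counts; the camera model is Poisson shot
# noise plus additive Gaussian read noise and a constant offset, and a small
# Gaussian PSF blur is applied before noise. The cargo channel is flat at the
# cytoplasm level inside each cell and elevated by that cell's true ratio
# inside the TGN, so the ground-truth per-cell ratio is exactly the planted
# Normal(r_eff, cell_sd) draw.

#' Rendering parameters
#'
#' Geometry ranges are uniform draws per cell (pixel units, ~0.65 um/px at
#' 20x); intensity levels are expected photon counts chosen to give realistic
#' signal-to-noise (shot-noise CV of a few percent at the cytoplasm level).
#'
#' @param cell_a,cell_b ranges of the cell semi-axes (px, at 20x).
#' @param scale magnification scale applied to the geometry ranges: 1 for
#'   20x imaging (fibroblasts), ~1.5-2 for 40x (SH-SY5Y cells, neurons),
#'   where each structure spans proportionally more pixels.
#' @param nucleus_scale nucleus semi-axes as a fraction of the cell's.
#' @param tgn_frac range of the TGN area as a fraction of cell area.
#' @param blur_sigma PSF Gaussian SD (px).
#' @param read_noise_sd camera read noise SD (counts).
#' @param camera_offset constant camera offset (counts); 0 corresponds to
#'   dark-corrected images, on which the intensity-ratio contract holds.
#' @param levels named intensity levels (counts).
#' @return list of rendering parameters.
#' @export
render_params <- function(cell_a = c(14, 22), cell_b = c(10, 16),
                          scale = 1,
                          nucleus_scale = 0.45, tgn_frac = c(0.05, 0.15),
                          blur_sigma = 0.5, read_noise_sd = 2,
                          camera_offset = 0,
                          levels = list(bg = 4, nucleus = 120, cellbody = 80,
                                        tgn_in_cell = 12, tgn = 150,
                                        cargo_cyto = 60, cargo_bg = 2)) {
  p <- as.list(environment())
  p$cell_a <- p$cell_a * scale
  p$cell_b <- p$cell_b * scale
  p
}

# membership test of pixels in a rotated ellipse
.in_ellipse <- function(rows, cols, cy, cx, a, b, theta) {
  dy <- rows - cy; dx <- cols - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render one synthetic field
#'
#' @param preset a `genotype_preset`.
#' @param n_cells number of cells to place.
#' @param effect optional `compound_effect` applied at `dose`.
#' @param dose dose in uM.
#' @param image_shape c(rows, cols), at least 64 x 64.
#' @param seed integer seed.
#' @param params from [render_params()].
#' @param well,field metadata for the produced `field_image`.
#' @return list with elements `field` (a `field_image`) and `truth` (list:
#'   `cells` data.frame with cell_id, centroid_row, centroid_col,
#'   true_ratio; `labels` list of nucleus/cell/tgn label matrices;
#'   `mean_ratio`, `n_cells`).
#' @export
render_field <- function(preset, n_cells, effect = NULL, dose = 0,
                         image_shape = c(256, 256), seed = 0,
                         params = render_params(), well = "A01", field = 1L) {
  stopifnot(n_cells >= 0, all(image_shape >= 64))
  nr <- image_shape[1]; nc <- image_shape[2]
  r_eff <- effective_ratio(preset, effect, dose)
  af_add <- if (!is.null(effect) && effect$autofluorescent)
    effect$af_slope * dose else 0

  with_seed(seed, {
    nuc_lab <- matrix(0L, nr, nc); cell_lab <- matrix(0L, nr, nc)
    tgn_lab <- matrix(0L, nr, nc)
    cells <- list()
    if (n_cells > 0) {
      a_max <- params$cell_a[2]
      margin <- a_max + 2
      min_sep <- 2 * a_max + 3
      centers <- matrix(numeric(0), 0, 2)
      tries <- 0; max_tries <- 400 * n_cells
      while (nrow(centers) < n_cells) {
        tries <- tries + 1
        if (tries > max_tries)
          stop_tgn("tgn_placement_error",
                   "could not place %d non-overlapping cells in %dx%d",
                   n_cells, nr, nc)
        cy <- stats::runif(1, margin, nr - margin)
        cx <- stats::runif(1, margin, nc - margin)
        if (nrow(centers) == 0 ||
            min((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >= min_sep^2)
          centers <- rbind(centers, c(cy, cx))
      }
      true_ratio <- pmax(stats::rnorm(n_cells, r_eff, preset$cell_sd), 0.05)
      for (i in seq_len(n_cells)) {
        cy <- centers[i, 1]; cx <- centers[i, 2]
        a <- stats::runif(1, params$cell_a[1], params$cell_a[2])
        b <- stats::runif(1, params$cell_b[1], params$cell_b[2])
        theta <- stats::runif(1, 0, pi)
        na_ <- a * params$nucleus_scale; nb_ <- b * params$nucleus_scale
        # bounding box
        rr <- max(1, floor(cy - a - 2)):min(nr, ceiling(cy + a + 2))
        cc <- max(1, floor(cx - a - 2)):min(nc, ceiling(cx + a + 2))
        grid_r <- matrix(rr, length(rr), length(cc))
        grid_c <- matrix(cc, length(rr), length(cc), byrow = TRUE)
        in_cell <- .in_ellipse(grid_r, grid_c, cy, cx, a, b, theta)
        in_nuc <- .in_ellipse(grid_r, grid_c, cy, cx, na_, nb_, theta)
        # perinuclear crescent: an annular wedge hugging the nucleus, sized
        # so its area is ~frac of the cell area while staying several px
        # wide (thin structures would be washed out by the PSF)
        phi <- stats::runif(1, 0, 2 * pi)
        frac <- stats::runif(1, params$tgn_frac[1], params$tgn_frac[2])
        w_half <- 0.8  # wedge half-angle (rad)
        s2 <- 1 + frac * pi * a * b / (w_half * na_ * nb_)
        s <- min(sqrt(s2), 0.95 / params$nucleus_scale)
        ann <- .in_ellipse(grid_r, grid_c, cy, cx, na_ * s, nb_ * s, theta) &
          !in_nuc
        ang <- atan2(grid_r - cy, grid_c - cx)
        wedge <- abs(atan2(sin(ang - phi), cos(ang - phi))) <= w_half
        in_tgn <- ann & wedge & in_cell
        if (!any(in_tgn)) in_tgn <- ann & in_cell  # pathological geometry
        cell_lab[rr, cc][in_cell] <- i
        nuc_lab[rr, cc][in_nuc] <- i
        tgn_lab[rr, cc][in_tgn] <- i
        cells[[i]] <- data.frame(cell_id = i, centroid_row = cy,
                                 centroid_col = cx, true_ratio = true_ratio[i])
      }
    }
    lv <- params$levels
    nucleus_ch <- matrix(lv$bg, nr, nc); nucleus_ch[nuc_lab > 0] <- lv$nucleus
    cell_ch <- matrix(lv$bg, nr, nc); cell_ch[cell_lab > 0] <- lv$cellbody
    tgn_ch <- matrix(lv$bg, nr, nc)
    tgn_ch[cell_lab > 0] <- lv$tgn_in_cell
    tgn_ch[tgn_lab > 0] <- lv$tgn
    cargo_ch <- matrix(lv$cargo_bg, nr, nc)
    if (n_cells > 0) {
      tr <- vapply(cells, function(x) x$true_ratio, numeric(1))
      inside <- cell_lab > 0
      cargo_ch[inside] <- lv$cargo_cyto
      tg <- tgn_lab > 0
      cargo_ch[tg] <- lv$cargo_cyto * tr[tgn_lab[tg]]
    }
    cargo_ch <- cargo_ch + af_add

    noisy <- function(m) {
      m <- gaussian_blur(m, params$blur_sigma)
      shot <- matrix(stats::rpois(length(m), as.vector(m)), nr, nc)
      pmax(shot + stats::rnorm(length(m), params$camera_offset,
                               params$read_noise_sd), 0)
    }
    fi <- field_image(list(nucleus = noisy(nucleus_ch),
                           cellbody = noisy(cell_ch),
                           tgn = noisy(tgn_ch),
                           cargo = noisy(cargo_ch)),
                      well = well, field = field)
    cells_df <- if (length(cells)) do.call(rbind, cells) else
      data.frame(cell_id = integer(), centroid_row = numeric(),
                 centroid_col = numeric(), true_ratio = numeric())
    list(field = fi,
         truth = list(cells = cells_df,
                      labels = list(nucleus = nuc_lab, cell = cell_lab,
                                    tgn = tgn_lab),
                      mean_ratio = if (nrow(cells_df)) mean(cells_df$true_ratio)
                                   else NA_real_,
                      n_cells = n_cells))
  })
}
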