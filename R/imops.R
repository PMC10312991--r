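# Low-level raster operations used by segmentation and rendering.
#
# Images are plain numeric matrices (row = y, column = x, 0-based pixel
# coordinates at measurement time). Everything is implemented with vectorized
# whole-matrix shifts; iteration counts scale with object diameter, not pixel
# count, which is fast enough for the field sizes this package targets
# (<= 1024 x 1024).

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

NEIGH4 <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
NEIGH8 <- c(NEIGH4, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))

#' Otsu threshold
#'
#' Histogram-based threshold maximizing between-class variance; returns the
#' threshold value (pixels strictly above it are foreground).
#'
#' @param x numeric matrix or vector of intensities.
#' @param nbins histogram resolution.
#' @return scalar threshold, or `NA` for a constant image.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (!is.finite(lo) || hi <= lo) return(NA_real_)
  edges <- seq(lo, hi, length.out = nbins + 1)
  h <- as.numeric(
    tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), nbins),
             nbins))
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

#' Connected-component labeling
#'
#' Iterative minimum-label propagation over 4- or 8-neighborhoods.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background, components numbered 1..n in
#'   row-major order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 4) {
  storage.mode(mask) <- "logical"
  .cc_label_cpp(mask, as.integer(connectivity))
}

#' Fill holes in a binary mask
#'
#' Background components not connected to the image border are set to
#' foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  storage.mode(mask) <- "logical"
  .fill_holes_cpp(mask)
}

#' City-block distance to background
#'
#' BFS distance transform: 0 on background, k on foreground pixels k
#' 4-connected steps from the nearest background pixel. Image borders count
#' as background.
#'
#' @param mask logical matrix.
#' @return numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  storage.mode(mask) <- "logical"
  .distance_transform_cpp(mask)
}

# Local maxima of `x` within a (2r+1)^2 window, restricted to x >= min_value.
local_maxima <- function(x, r = 2, min_value = 1) {
  mx <- x
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    mx <- pmax(mx, shift_mat(x, dr, dc, -Inf))
  }
  x >= mx & x >= min_value
}

#' Grow labeled seeds through a mask
#'
#' Watershed-style flooding: unlabeled foreground pixels are claimed in
#' order of decreasing `priority` (FIFO among equal priorities) by the
#' labeled region that reaches them first over 4-connectivity. Used both to
#' split touching nuclei (priority = distance transform) and to assign
#' cell-body pixels to their seeding nucleus (priority = smoothed cell-body
#' intensity). Fully deterministic.
#'
#' @param seeds integer label matrix (0 = unlabeled).
#' @param mask logical matrix restricting growth.
#' @param priority numeric matrix (default: constant, plain BFS).
#' @return integer label matrix; mask pixels unreachable from any seed
#'   stay 0.
#' @export
seeded_grow <- function(seeds, mask, priority = NULL) {
  if (is.null(priority)) priority <- matrix(0, nrow(mask), ncol(mask))
  storage.mode(mask) <- "logical"
  storage.mode(seeds) <- "integer"
  storage.mode(priority) <- "double"
  .seeded_grow_cpp(seeds, mask, priority)
}

#' Split touching objects by distance-transform watershed
#'
#' Markers are clustered local maxima of the city-block distance transform
#' (maxima closer than the window radius merge into one marker); each object
#' pixel is then assigned to a marker by seeded growing with the distance
#' as priority. Components whose interior never reaches `min_radius` keep a
#' single label.
#'
#' @param mask logical matrix of the objects.
#' @param min_radius minimum interior radius (px) for a split marker.
#' @return integer label matrix.
#' @export
watershed_split <- function(mask, min_radius = 3) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- distance_transform(mask)
  peaks <- local_maxima(d, r = max(2, ceiling(min_radius)),
                        min_value = min_radius)
  # merge peak clusters closer than ~min_radius so ridge plateaus of a
  # single elongated object yield one marker, not several
  merge_r <- max(2L, as.integer(min_radius))
  dil <- peaks
  for (k in seq_len(merge_r)) {
    nd <- dil
    for (sh in NEIGH8) nd <- nd | shift_mat(dil, sh[1], sh[2], FALSE)
    dil <- nd
  }
  markers <- label_components(dil & mask, connectivity = 8)
  markers[!peaks] <- 0L
  lab <- seeded_grow(markers, mask, priority = d)
  # components with no marker (too thin) keep one label each
  left <- mask & lab == 0L
  if (any(left)) {
    extra <- label_components(left, connectivity = 4)
    lab[left] <- extra[left] + max(lab)
  }
  lab
}

#' Separable Gaussian blur
#'
#' @param x numeric matrix.
#' @param sigma Gaussian SD in pixels; 0 returns `x` unchanged.
#' @return blurred matrix (renormalized at the borders).
#' @export
gaussian_blur <- function(x, sigma = 1) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma); w <- w / sum(w)
  ones <- matrix(1, nrow(x), ncol(x))
  acc <- matrix(0, nrow(x), ncol(x)); norm <- acc
  for (k in -r:r) {
    acc <- acc + w[k + r + 1] * shift_mat(x, 0, k, 0)
    norm <- norm + w[k + r + 1] * shift_mat(ones, 0, k, 0)
  }
  x1 <- acc / norm
  acc <- matrix(0, nrow(x), ncol(x)); norm <- acc
  for (k in -r:r) {
    acc <- acc + w[k + r + 1] * shift_mat(x1, k, 0, 0)
    norm <- norm + w[k + r + 1] * shift_mat(ones, k, 0, 0)
  }
  acc / norm
}

# Number of foreground-background pixel edges (image border counts as
# background). The Crofton-style perimeter is pi/4 times this count, exact
# in expectation for smooth convex shapes (e.g. a digital disk of radius r
# has ~8r boundary edges -> perimeter ~2*pi*r).
boundary_edge_count <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1L
  h <- sum(abs(m[, -1] - m[, -ncol(m)]))
  v <- sum(abs(m[-1, ] - m[-nrow(m), ]))
  h + v
}

#' Crofton perimeter of a binary region
#' @param mask logical matrix.
#' @return perimeter estimate in pixel units.
#' @export
perimeter_crofton <- function(mask) (pi / 4) * boundary_edge_count(mask)

# Moment-based best-fit ellipse of a pixel set. Returns full axis lengths
# (length >= width) and eccentricity. A 1/12 term accounts for the spread of
# intensity within each unit pixel so thin/small regions stay nondegenerate.
ellipse_axes <- function(rows, cols) {
  n <- length(rows)
  mu_rr <- sum((rows - mean(rows))^2) / n + 1 / 12
  mu_cc <- sum((cols - mean(cols))^2) / n + 1 / 12
  mu_rc <- sum((rows - mean(rows)) * (cols - mean(cols))) / n
  tr <- mu_rr + mu_cc
  det_ <- mu_rr * mu_cc - mu_rc^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  list(length = 4 * sqrt(l1), width = 4 * sqrt(l2),
       eccentricity = sqrt(max(1 - l2 / max(l1, .Machine$double.eps), 0)))
}

# Convex-hull area of a pixel set (pixels as unit squares approximated by
# their centers; shoelace formula). Guards degenerate (collinear) sets.
convex_area <- function(rows, cols) {
  if (length(rows) < 3) return(length(rows))
  pts <- unique(cbind(cols, rows))
  if (nrow(pts) < 3) return(length(rows))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  xs <- pts[h, 1]; ys <- pts[h, 2]
  a <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  max(a, length(rows))  # hull of pixel centers can undercut the pixel area
}
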