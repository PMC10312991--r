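# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# one rendered KO field plus segmentation and measurements, reused widely
ko_field_fixture <- function() {
  cached("ko_field", {
    rf <- render_field(tgn_presets("shsy5y_atg9a")$negative, n_cells = 12,
                       seed = 42)
    seg <- segment_field(rf$field)
    cells <- measure_cells(rf$field, seg)
    list(rf = rf, seg = seg, cells = cells)
  })
}

# a filled disk mask of radius r
disk_mask <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  g <- expand.grid(row = 1:n, col = 1:n)
  m <- matrix((g$row - ctr)^2 + (g$col - ctr)^2 <= r^2, n, n)
  m
}

# a filled axis-aligned ellipse mask with semi-axes a (cols) and b (rows)
ellipse_mask <- function(a, b, pad = 4) {
  nr <- 2 * (b + pad) + 1; nc <- 2 * (a + pad) + 1
  cy <- b + pad + 1; cx <- a + pad + 1
  rowm <- matrix(seq_len(nr), nr, nc)
  colm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((colm - cx) / a)^2 + ((rowm - cy) / b)^2 <= 1
}

# hand-built one-cell field + segmentation for compartment-mean oracles:
# cargo values are set explicitly on known TGN / cytoplasm pixels
toy_cell <- function(tgn_values = c(10, 20), cyto_values = c(5, 5, 5, 5)) {
  n <- 8
  z <- matrix(0L, n, n)
  cell <- z; tgn <- z; nuc <- z
  # cell occupies row 4, columns 2..(1+k)
  k <- length(tgn_values) + length(cyto_values)
  cols <- seq(2, 1 + k)
  cell[4, cols] <- 1L
  tgn[4, cols[seq_along(tgn_values)]] <- 1L
  nuc[4, cols[length(cols)]] <- 1L
  cargo <- matrix(1, n, n)
  cargo[4, cols] <- c(tgn_values, cyto_values)
  f <- field_image(list(nucleus = matrix(1, n, n), cellbody = matrix(1, n, n),
                        tgn = matrix(1, n, n), cargo = cargo))
  seg <- structure(list(nucleus_labels = nuc, cell_labels = cell,
                        tgn_labels = tgn, params = segment_params(),
                        blank = FALSE),
                   class = "segmentation_result")
  list(field = f, seg = seg)
}
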