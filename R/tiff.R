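# Minimal multi-page TIFF I/O.
#
# Fields are exchanged as uncompressed little-endian 16-bit grayscale
# multi-page TIFFs (one page per channel, channel order: nucleus, cell-body,
# TGN, cargo) plus a JSON sidecar with pixel size and channel names. No TIFF
# library ships with this R stack, so the small strict subset needed here
# (baseline TIFF, one strip per page) is implemented directly; files are
# readable by any standard TIFF reader.

.tiff_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    if (type == 3)
      c(writeBin(as.integer(value), raw(), size = 2, endian = "little"),
        as.raw(c(0, 0)))
    else writeBin(as.integer(value), raw(), size = 4, endian = "little"))
}

#' Write matrices as a multi-page 16-bit TIFF
#'
#' @param channels list of numeric matrices (equal dimensions); values are
#'   clamped to 0..65535 and rounded.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(channels, path) {
  stopifnot(length(channels) >= 1)
  dims <- dim(channels[[1]])
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  n_pages <- length(channels)
  h <- dims[1]; w <- dims[2]
  bytes_per_page <- 2L * h * w
  n_entries <- 9L
  ifd_size <- 2L + 12L * n_entries + 4L
  # layout: [8-byte header][page1 data][page1 IFD][page2 data][page2 IFD]...
  first_ifd <- 8L + bytes_per_page
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  offset <- 8L
  for (p in seq_len(n_pages)) {
    m <- channels[[p]]
    stopifnot(identical(dim(m), dims))
    v <- as.integer(pmin(pmax(round(t(m)), 0), 65535))
    writeBin(v, con, size = 2, endian = "little", useBytes = TRUE)
    data_off <- offset
    ifd_off <- data_off + bytes_per_page
    next_ifd <- if (p < n_pages) ifd_off + ifd_size + bytes_per_page else 0L
    ifd <- c(
      writeBin(as.integer(n_entries), raw(), size = 2, endian = "little"),
      .tiff_entry(256, 4, 1, w),            # ImageWidth
      .tiff_entry(257, 4, 1, h),            # ImageLength
      .tiff_entry(258, 3, 1, 16),           # BitsPerSample
      .tiff_entry(259, 3, 1, 1),            # Compression: none
      .tiff_entry(262, 3, 1, 1),            # Photometric: BlackIsZero
      .tiff_entry(273, 4, 1, data_off),     # StripOffsets
      .tiff_entry(277, 3, 1, 1),            # SamplesPerPixel
      .tiff_entry(278, 4, 1, h),            # RowsPerStrip
      .tiff_entry(279, 4, 1, bytes_per_page), # StripByteCounts
      writeBin(as.integer(next_ifd), raw(), size = 4, endian = "little")
    )
    writeBin(ifd, con)
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

.read_u <- function(r, at, size) {
  # unsigned little-endian integer from raw vector `r` at 1-based offset `at`
  sum(as.integer(r[at:(at + size - 1)]) * 256^(0:(size - 1)))
}

#' Read a multi-page TIFF written by [write_tiff()]
#'
#' Supports baseline little-endian uncompressed grayscale TIFFs (8 or 16 bit,
#' any strip layout with contiguous strips).
#'
#' @param path TIFF file.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(r[1:2]) != "II" || .read_u(r, 3, 2) != 42)
    stop_tgn("tgn_io_error", "not a little-endian TIFF: %s", path)
  ifd <- .read_u(r, 5, 4)
  pages <- list()
  while (ifd != 0) {
    n <- .read_u(r, ifd + 1, 2)
    tags <- list()
    for (i in seq_len(n)) {
      at <- ifd + 3 + (i - 1) * 12
      tag <- .read_u(r, at, 2)
      type <- .read_u(r, at + 2, 2)
      cnt <- .read_u(r, at + 4, 4)
      val <- if (type == 3 && cnt == 1) .read_u(r, at + 8, 2)
             else .read_u(r, at + 8, 4)
      tags[[as.character(tag)]] <- val
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- tags[["258"]] %||% 1
    if ((tags[["259"]] %||% 1) != 1)
      stop_tgn("tgn_io_error", "compressed TIFF not supported")
    off <- tags[["273"]]; nbytes <- tags[["279"]] %||% (h * w * bits / 8)
    bytes <- r[(off + 1):(off + nbytes)]
    size <- bits / 8
    v <- readBin(bytes, "integer", n = h * w, size = size,
                 signed = size > 2, endian = "little")
    if (size <= 2) v[v < 0] <- v[v < 0] + 2^bits
    pages[[length(pages) + 1]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    ifd <- .read_u(r, ifd + 3 + n * 12, 4)
  }
  pages
}

#' Construct a field image
#'
#' One imaging field: four co-registered intensity channels plus metadata.
#'
#' @param channels named list of 4 nonnegative numeric matrices, in order
#'   nucleus, cell-body, TGN, cargo.
#' @param pixel_size_um pixel size in micrometers.
#' @param well well id.
#' @param field field index within the well.
#' @return an object of class `field_image`.
#' @export
field_image <- function(channels,
                        pixel_size_um = 0.65, well = "A01", field = 1L) {
  stopifnot(length(channels) == 4)
  if (is.null(names(channels)) || any(names(channels) == ""))
    names(channels) <- c("nucleus", "cellbody", "tgn", "cargo")
  dims <- dim(channels[[1]])
  for (ch in channels) {
    stopifnot(identical(dim(ch), dims))
    if (any(!is.finite(ch)) || any(ch < 0))
      stop_tgn("tgn_config_error", "channel intensities must be finite and >= 0")
  }
  structure(list(channels = channels, channel_names = names(channels),
                 pixel_size_um = pixel_size_um, well = well,
                 field = as.integer(field)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> well %s field %d: %dx%d px, channels %s\n",
              x$well, x$field, d[1], d[2],
              paste(x$channel_names, collapse = "/")))
  invisible(x)
}

#' Write / read a field image (TIFF + JSON sidecar)
#'
#' @param field a `field_image`.
#' @param path path to the `.tif` file; the sidecar is written next to it
#'   with extension `.json`.
#' @return `read_field` returns a `field_image`.
#' @export
write_field <- function(field, path) {
  write_tiff(field$channels, path)
  sidecar <- sub("\\.tiff?$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(channel_names = field$channel_names,
         pixel_size_um = field$pixel_size_um,
         well = field$well, field = field$field),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  pages <- read_tiff(path)
  sidecar <- sub("\\.tiff?$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  nm <- unlist(meta$channel_names) %||% c("nucleus", "cellbody", "tgn", "cargo")
  names(pages) <- nm[seq_along(pages)]
  field_image(pages,
              pixel_size_um = meta$pixel_size_um %||% 0.65,
              well = meta$well %||% "A01",
              field = meta$field %||% 1L)
}
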