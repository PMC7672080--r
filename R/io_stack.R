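# Minimal multi-page TIFF codec for image stacks: baseline TIFF 6.0,
# little-endian, uncompressed, 16-bit unsigned grayscale, one strip per
# page.  Hand-rolled because no TIFF package is available in the target
# environment; covered by round-trip tests.

tif_u16 <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "little")
tif_u32 <- function(v) writeBin(as.integer(v), raw(), size = 4L, endian = "little")

# One 12-byte IFD entry: tag, type (3 = SHORT, 4 = LONG), count, value.
ifd_entry <- function(tag, type, count, value) {
  val <- if (type == 3L) c(tif_u16(value), tif_u16(0L)) else tif_u32(value)
  c(tif_u16(tag), tif_u16(type), tif_u32(count), val)
}

#' Write an image stack as multi-page TIFF
#'
#' 16-bit unsigned grayscale, frame order = time order.  Values are rounded
#' and clipped to \[0, 65535\]; saturation triggers a warning.
#'
#' @param stack A numeric matrix (single frame) or list of matrices
#'   (frames), all the same size; matrix row = y, column = x.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  stopifnot(length(stack) >= 1L)
  ny <- nrow(stack[[1L]]); nx <- ncol(stack[[1L]])
  for (fr in stack) stopifnot(nrow(fr) == ny, ncol(fr) == nx)
  vals <- lapply(stack, function(fr) {
    v <- round(fr)
    if (any(v > 65535 | v < 0))
      warning("pixel values outside [0, 65535] clipped at saturation")
    pmin(pmax(v, 0), 65535)
  })

  n_entries <- 8L
  ifd_size <- 2L + 12L * n_entries + 4L
  strip_size <- 2L * nx * ny
  page_size <- ifd_size + strip_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), tif_u16(42L), tif_u32(8L)), con)
  for (i in seq_along(vals)) {
    ifd_off <- 8L + (i - 1L) * page_size
    strip_off <- ifd_off + ifd_size
    next_ifd <- if (i < length(vals)) ifd_off + page_size else 0L
    entries <- c(
      ifd_entry(256L, 3L, 1L, nx),          # ImageWidth
      ifd_entry(257L, 3L, 1L, ny),          # ImageLength
      ifd_entry(258L, 3L, 1L, 16L),         # BitsPerSample
      ifd_entry(259L, 3L, 1L, 1L),          # Compression: none
      ifd_entry(262L, 3L, 1L, 1L),          # Photometric: BlackIsZero
      ifd_entry(273L, 4L, 1L, strip_off),   # StripOffsets
      ifd_entry(278L, 3L, 1L, ny),          # RowsPerStrip
      ifd_entry(279L, 4L, 1L, strip_size))  # StripByteCounts
    writeBin(c(tif_u16(n_entries), entries, tif_u32(next_ifd)), con)
    # row-major pixel order: transpose the column-major R matrix
    px <- as.integer(t(vals[[i]]))
    px[px >= 32768L] <- px[px >= 32768L] - 65536L   # reinterpret as signed
    writeBin(px, con, size = 2L, endian = "little")
  }
  invisible(path)
}

rd_u16 <- function(raw, at, n = 1L) {
  v <- readBin(raw[at:(at + 2L * n - 1L)], "integer", n, size = 2L,
               signed = FALSE, endian = "little")
  v
}
rd_u32 <- function(raw, at, n = 1L) {
  v <- readBin(raw[at:(at + 4L * n - 1L)], "integer", n, size = 4L,
               endian = "little")
  ifelse(v < 0, v + 2^32, v)
}

#' Read a multi-page TIFF stack
#'
#' Understands the subset written by [write_stack()] (and common baseline
#' grayscale files): little-endian, uncompressed, 8- or 16-bit, single
#' sample per pixel, any strip layout.
#'
#' @param path TIFF file.
#' @return List of numeric matrices, one per frame (row = y, column = x).
#' @export
read_stack <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L || rawToChar(raw[1:2]) != "II" || rd_u16(raw, 3L) != 42L)
    stop("'", path, "': not a little-endian TIFF file")
  frames <- list()
  ifd_off <- rd_u32(raw, 5L)
  while (ifd_off != 0) {
    at <- ifd_off + 1L
    n_entries <- rd_u16(raw, at)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- at + 2L + 12L * (e - 1L)
      tag <- rd_u16(raw, base)
      type <- rd_u16(raw, base + 2L)
      count <- rd_u32(raw, base + 4L)
      value <- if (type == 3L && count == 1L) rd_u16(raw, base + 8L)
      else if (count == 1L) rd_u32(raw, base + 8L)
      else {  # out-of-line value array
        off <- rd_u32(raw, base + 8L)
        if (type == 3L) rd_u16(raw, off + 1L, count) else rd_u32(raw, off + 1L, count)
      }
      tags[[as.character(tag)]] <- value
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("'", path, "': missing required TIFF tag ", tag)
        default
      } else v
    }
    nx <- need(256L); ny <- need(257L)
    bits <- need(258L, 8L)[1L]
    if (need(259L, 1L) != 1L) stop("'", path, "': compressed TIFF not supported")
    offs <- need(273L)
    counts <- need(279L, nx * ny * bits / 8L)
    bytes <- raw(0)
    for (s in seq_along(offs))
      bytes <- c(bytes, raw[(offs[s] + 1L):(offs[s] + counts[s])])
    px <- readBin(bytes, "integer", nx * ny, size = bits / 8L,
                  signed = FALSE, endian = "little")
    frames[[length(frames) + 1L]] <- matrix(px, ny, nx, byrow = TRUE)
    ifd_off <- rd_u32(raw, at + 2L + 12L * n_entries)
  }
  frames
}
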