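# Region-file readers/writers: ImageJ .roi (binary polygon/rectangle
# records) and a plain polygon_text dialect as the portable fallback.
#
# Region kinds are assigned from names: a name containing "cell" or
# "outline" (case-insensitive) becomes the cell outline, a name containing
# "contact" becomes a contact, anything else a generic ROI.

kind_from_name <- function(name) {
  n <- tolower(name)
  if (grepl("cell|outline", n)) "cell_outline"
  else if (grepl("contact", n)) "contact"
  else "generic_roi"
}

# --- ImageJ .roi -----------------------------------------------------------

read_u16 <- function(raw, at) 256L * as.integer(raw[at]) + as.integer(raw[at + 1L])
read_s16 <- function(raw, at) {
  v <- read_u16(raw, at)
  if (v >= 32768L) v - 65536L else v
}

# Parse one ImageJ .roi file (polygon, freehand, traced or rectangle record
# types).  Returns list(name, vertices) with vertices in pixel coordinates.
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("'", path, "': not an ImageJ .roi file (missing 'Iout' magic)")
  type <- as.integer(raw[7L])
  top <- read_s16(raw, 9L); left <- read_s16(raw, 11L)
  bottom <- read_s16(raw, 13L); right <- read_s16(raw, 15L)
  n <- read_u16(raw, 17L)
  name <- sub("\\.roi$", "", basename(path))
  if (type == 1L) {                          # rectangle
    verts <- cbind(c(left, right, right, left), c(top, top, bottom, bottom))
  } else if (type %in% c(0L, 7L, 8L)) {      # polygon, freehand, traced
    if (n < 3L)
      stop("'", path, "': polygon record with ", n, " vertices (need >= 3)")
    if (length(raw) < 64L + 4L * n)
      stop("'", path, "': truncated coordinate block")
    xs <- vapply(seq_len(n), function(i) read_s16(raw, 64L + 2L * (i - 1L) + 1L),
                 integer(1))
    ys <- vapply(seq_len(n), function(i) read_s16(raw, 64L + 2L * n + 2L * (i - 1L) + 1L),
                 integer(1))
    verts <- cbind(left + xs, top + ys)
  } else {
    stop("'", path, "': unsupported ROI type ", type,
         " (only polygon and rectangle records are handled)")
  }
  list(name = name, vertices = verts)
}

#' Write an ImageJ .roi polygon file
#'
#' Emits the minimal binary polygon record understood by ImageJ and by
#' [load_regions()]; vertex coordinates are integer pixels.
#'
#' @param vertices n x 2 integer matrix of pixel coordinates.
#' @param path Output path.
#' @param type `"polygon"` or `"rect"` (rectangles store only the bounding
#'   box).
#' @return `path`, invisibly.
#' @export
write_imagej_roi <- function(vertices, path, type = c("polygon", "rect")) {
  type <- match.arg(type)
  vertices <- round(rbind(vertices))
  left <- min(vertices[, 1L]); top <- min(vertices[, 2L])
  right <- max(vertices[, 1L]); bottom <- max(vertices[, 2L])
  n <- nrow(vertices)
  u16 <- function(v) as.raw(c(v %/% 256L %% 256L, v %% 256L))
  hdr <- raw(64L)
  hdr[1:4] <- charToRaw("Iout")
  hdr[5:6] <- u16(227L)                       # format version
  hdr[7L] <- as.raw(if (type == "rect") 1L else 0L)
  hdr[9:10] <- u16(top); hdr[11:12] <- u16(left)
  hdr[13:14] <- u16(bottom); hdr[15:16] <- u16(right)
  hdr[17:18] <- u16(if (type == "rect") 0L else n)
  body <- if (type == "rect") raw(0) else
    as.raw(unlist(lapply(c(vertices[, 1L] - left, vertices[, 2L] - top),
                         function(v) c(v %/% 256L %% 256L, v %% 256L))))
  writeBin(c(hdr, body), path)
  invisible(path)
}

# --- polygon_text ----------------------------------------------------------

# Dialect: one region per block, blocks separated by blank lines.  First
# line of a block: "<name> <kind>" (kind optional, inferred from the name
# if absent); remaining lines: "x y" vertex pairs in pixel coordinates.
# Lines starting with '#' are comments.
read_polygon_text <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!startsWith(lines, "#")]
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[vapply(blocks, length, integer(1)) > 0L]
  lapply(blocks, function(b) {
    head <- strsplit(b[1L], "\\s+")[[1L]]
    name <- head[1L]
    kind <- if (length(head) >= 2L) head[2L] else kind_from_name(name)
    if (!kind %in% c("cell_outline", "contact", "generic_roi"))
      stop("'", path, "', region '", name, "': unknown kind '", kind, "'")
    coords <- lapply(b[-1L], function(ln) {
      v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
      if (length(v) != 2L || anyNA(v))
        stop("'", path, "', region '", name, "': malformed vertex line '",
             ln, "'")
      v
    })
    if (length(coords) < 3L)
      stop("'", path, "', region '", name, "': polygon with ",
           length(coords), " vertices (need >= 3)")
    list(name = name, kind = kind, vertices = do.call(rbind, coords))
  })
}

#' Write regions as polygon_text
#'
#' @param g `smf_geometry`; vertices are written in pixel coordinates
#'   (um / pixel_size).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygon_text <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# polygon_text regions, coordinates in pixels",
               sprintf("# pixel_size_um %g", g$pixel_size)), con)
  for (r in c(list(g$cell_outline), g$sub_regions)) {
    writeLines("", con)
    writeLines(paste(r$name, r$kind), con)
    px <- r$polygon / g$pixel_size
    writeLines(sprintf("%.6f %.6f", px[, 1L], px[, 2L]), con)
  }
  invisible(path)
}

# --- loader ----------------------------------------------------------------

#' Load a cell geometry from region files
#'
#' Reads regions in either dialect, scales pixel coordinates to um with
#' `pixel_size`, assigns region kinds from the naming convention (names
#' containing "cell"/"outline" -> cell outline, "contact" -> contact,
#' otherwise generic ROI) and assembles an `smf_geometry`.  Behaviour
#' parameters are filled from the `D_out`/`D_in`/... defaults by kind.
#'
#' @param path One polygon_text file, or a character vector of `.roi` files
#'   (one region each).
#' @param dialect `"polygon_text"` or `"roi"`.
#' @param pixel_size Micrometers per pixel.
#' @param D_out,D_in,D_trap,k_on,k_off,P_crossing Behaviour defaults applied
#'   by kind (outline gets `D_out`; contacts get the rest).
#' @return `smf_geometry`.
#' @export
load_regions <- function(path, dialect = c("polygon_text", "roi"),
                         pixel_size = 0.16, D_out = 0.3, D_in = 0.3,
                         D_trap = 0.04, k_on = 0.15, k_off = 0.015,
                         P_crossing = 0.3) {
  dialect <- match.arg(dialect)
  for (p in path) if (!file.exists(p)) stop("file not found: ", p)
  recs <- if (dialect == "roi") {
    lapply(path, function(p) {
      r <- read_imagej_roi(p)
      list(name = r$name, kind = kind_from_name(r$name), vertices = r$vertices)
    })
  } else {
    if (length(path) != 1L) stop("polygon_text dialect expects a single file")
    read_polygon_text(path)
  }
  outline <- NULL; subs <- list()
  for (r in recs) {
    poly_um <- r$vertices * pixel_size
    if (r$kind == "cell_outline") {
      if (!is.null(outline)) stop("more than one cell_outline region")
      outline <- region(r$name, poly_um, kind = "cell_outline", D_free = D_out)
    } else {
      trapping <- r$kind == "contact"
      subs[[length(subs) + 1L]] <-
        region(r$name, poly_um, kind = r$kind, D_free = D_in,
               D_trap = D_trap, k_on = if (trapping) k_on else 0,
               k_off = if (trapping) k_off else 0, P_crossing = P_crossing)
    }
  }
  if (is.null(outline))
    stop("no cell_outline region found (name one region 'cell' or 'outline')")
  geometry(outline, subs, pixel_size = pixel_size)
}
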