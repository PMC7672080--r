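# Geometry: polygon regions in micrometers and particle-boundary interactions.
#
# Coordinate convention: continuous micrometers, origin at the top-left corner
# of the reference raster, x rightward, y downward.  Pixel (i, j) covers the
# half-open square [i*s, (i+1)*s) x [j*s, (j+1)*s) where s is the pixel size.

#' Create a polygon region
#'
#' A region is a closed, non-self-intersecting polygon in micrometers carrying
#' the behaviour profile of the molecules it contains: diffusion coefficients
#' for the free and trapped states, first-order binding/unbinding rates, and
#' the probability that a Brownian step across its border is accepted rather
#' than bounced.
#'
#' @param name Region label.
#' @param polygon Numeric matrix (n x 2) of vertices in micrometers, ordered
#'   along the boundary; the closing edge from the last vertex back to the
#'   first is implicit.
#' @param kind One of `"cell_outline"`, `"contact"`, `"generic_roi"`.
#' @param D_free Diffusion coefficient of unbound molecules inside, um^2/s.
#' @param D_trap Diffusion coefficient while bound, um^2/s.
#' @param k_on Binding rate inside the region, 1/s (0 for non-trapping).
#' @param k_off Unbinding rate, 1/s.
#' @param P_crossing Probability in \[0, 1\] that an attempted border crossing
#'   succeeds; the complement models steric hindrance at narrow junctions.
#' @return An object of class `smf_region`.
#' @export
region <- function(name, polygon, kind = c("generic_roi", "cell_outline", "contact"),
                   D_free = 0.3, D_trap = 0.04, k_on = 0, k_off = 0,
                   P_crossing = 1) {
  kind <- match.arg(kind)
  polygon <- as.matrix(polygon)
  dimnames(polygon) <- NULL
  if (!is.numeric(polygon) || ncol(polygon) != 2L)
    stop("'polygon' must be a numeric n x 2 matrix of vertices")
  if (nrow(polygon) >= 2L &&
      all(abs(polygon[1L, ] - polygon[nrow(polygon), ]) < 1e-12))
    polygon <- polygon[-nrow(polygon), , drop = FALSE]  # drop explicit closure
  if (nrow(polygon) < 3L)
    stop("region '", name, "': polygon must have at least 3 vertices")
  if (abs(polygon_area(polygon)) <= 0)
    stop("region '", name, "': polygon has zero area")
  stopifnot(D_free >= 0, D_trap >= 0, k_on >= 0, k_off >= 0,
            P_crossing >= 0, P_crossing <= 1)
  structure(list(name = as.character(name), polygon = polygon, kind = kind,
                 D_free = D_free, D_trap = D_trap, k_on = k_on, k_off = k_off,
                 P_crossing = P_crossing),
            class = "smf_region")
}

#' Polygon area by the shoelace formula
#'
#' @param polygon n x 2 vertex matrix (closing edge implicit).
#' @return Signed area is taken absolute; square micrometers for polygons in um.
#' @export
polygon_area <- function(polygon) {
  x <- polygon[, 1L]; y <- polygon[, 2L]
  xj <- c(x[-1L], x[1L]); yj <- c(y[-1L], y[1L])
  abs(sum(x * yj - xj * y)) / 2
}

#' Assemble a cell geometry
#'
#' @param cell_outline `smf_region` of kind `"cell_outline"`; molecules are
#'   reflected at its border and never leave it.
#' @param sub_regions List of `smf_region` objects (contacts and other ROIs),
#'   each fully inside the cell outline; assumed mutually disjoint.
#' @param pixel_size Micrometers per pixel of the reference image.
#' @param reference_image Optional raster matrix, kept as metadata.
#' @return Object of class `smf_geometry`.
#' @export
geometry <- function(cell_outline, sub_regions = list(), pixel_size = 0.16,
                     reference_image = NULL) {
  stopifnot(inherits(cell_outline, "smf_region"), pixel_size > 0)
  if (cell_outline$kind != "cell_outline")
    stop("'cell_outline' must be a region of kind 'cell_outline'")
  if (inherits(sub_regions, "smf_region")) sub_regions <- list(sub_regions)
  for (r in sub_regions) {
    stopifnot(inherits(r, "smf_region"))
    if (r$kind == "cell_outline")
      stop("only one cell_outline region is allowed")
    if (!all(point_in_region(r$polygon, cell_outline)))
      stop("sub-region '", r$name, "' is not contained in the cell outline")
  }
  structure(list(cell_outline = cell_outline, sub_regions = sub_regions,
                 pixel_size = pixel_size, reference_image = reference_image,
                 fast_rect = axis_rect_bounds(cell_outline$polygon)),
            class = "smf_geometry")
}

# If the polygon is an axis-aligned rectangle, return its bounds; the motion
# engine then uses exact folding reflection instead of polygon tests.
axis_rect_bounds <- function(poly) {
  if (nrow(poly) != 4L) return(NULL)
  xs <- sort(unique(poly[, 1L])); ys <- sort(unique(poly[, 2L]))
  if (length(xs) != 2L || length(ys) != 2L) return(NULL)
  ok <- all(apply(poly, 1L, function(v)
    v[1L] %in% xs && v[2L] %in% ys))
  if (!ok) return(NULL)
  list(x = xs, y = ys)
}

# Triangle-wave fold of coordinates into [lo, hi]: iterated specular
# reflection at the two walls, exact for any step length.
fold_reflect <- function(z, lo, hi) {
  L <- hi - lo
  z <- (z - lo) %% (2 * L)
  lo + ifelse(z > L, 2 * L - z, z)
}

#' @export
print.smf_geometry <- function(x, ...) {
  cat("<smf_geometry>\n")
  cat(sprintf("  cell outline '%s': %d vertices, area %.2f um^2\n",
              x$cell_outline$name, nrow(x$cell_outline$polygon),
              polygon_area(x$cell_outline$polygon)))
  for (r in x$sub_regions)
    cat(sprintf("  %s '%s': area %.2f um^2, D_free %.3g, D_trap %.3g, k_on %.3g, k_off %.3g, P_cross %.2f\n",
                r$kind, r$name, polygon_area(r$polygon), r$D_free, r$D_trap,
                r$k_on, r$k_off, r$P_crossing))
  cat(sprintf("  pixel size %.3g um\n", x$pixel_size))
  invisible(x)
}

# Vectorized even-odd (ray casting) containment test.  Points lying exactly on
# an edge count as inside: deterministic tie-break so border molecules are
# never in limbo.  `eps` is the absolute tolerance of the on-edge test.
# A bounding-box prefilter keeps the cost proportional to the number of
# points near the polygon, which matters when small contacts sit in a large
# cell outline.
point_in_polygon <- function(px, py, polygon, eps = 1e-9) {
  out <- logical(length(px))
  xr <- range(polygon[, 1L]); yr <- range(polygon[, 2L])
  cand <- which(px >= xr[1L] - eps & px <= xr[2L] + eps &
                py >= yr[1L] - eps & py <= yr[2L] + eps)
  if (length(cand) == 0L) return(out)
  full <- length(cand) == length(px)
  if (!full) { px <- px[cand]; py <- py[cand] }
  nv <- nrow(polygon)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- polygon[i, 1L]; yi <- polygon[i, 2L]
    xj <- polygon[j, 1L]; yj <- polygon[j, 2L]
    if (yj != yi) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    # on-segment: |cross product| small and within the segment's bounding box
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    seg_len <- sqrt((xj - xi)^2 + (yj - yi)^2)
    on <- abs(cr) <= eps * max(seg_len, 1) &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    on_edge <- on_edge | on
    j <- i
  }
  out[cand] <- inside | on_edge
  out
}

#' Point-in-region containment test
#'
#' Even-odd (ray casting) rule; points exactly on an edge count as inside.
#'
#' @param p Numeric vector `c(x, y)` or an n x 2 matrix of positions in um.
#' @param r `smf_region`.
#' @return Logical vector, one element per point.
#' @export
point_in_region <- function(p, r) {
  stopifnot(inherits(r, "smf_region"))
  p <- rbind(p)
  point_in_polygon(p[, 1L], p[, 2L], r$polygon)
}

# Index (0 = none) of the first sub-region containing each point.
region_index <- function(px, py, g) {
  idx <- integer(length(px))
  for (k in seq_along(g$sub_regions)) {
    unassigned <- idx == 0L
    if (!any(unassigned)) break
    hit <- point_in_polygon(px[unassigned], py[unassigned],
                            g$sub_regions[[k]]$polygon)
    idx[unassigned][hit] <- k
  }
  idx
}

# Reflect points (px, py) across the infinite line through (ax, ay)-(bx, by).
reflect_across_edge <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  fx <- ax + t * dx; fy <- ay + t * dy      # foot of perpendicular
  cbind(2 * fx - px, 2 * fy - py)
}

# For segments p0 -> p1 known to end outside the polygon, find the first edge
# intersected and specularly reflect p1 across it.  Returns the reflected
# points; rows with no intersection found (numerical corner cases) are NA.
reflect_at_outline <- function(x0, y0, x1, y1, polygon) {
  n <- length(x0)
  nv <- nrow(polygon)
  tmin <- rep(Inf, n)
  ei <- rep(NA_integer_, n)
  j <- nv
  for (i in seq_len(nv)) {
    ax <- polygon[j, 1L]; ay <- polygon[j, 2L]
    bx <- polygon[i, 1L]; by <- polygon[i, 2L]
    rx <- x1 - x0; ry <- y1 - y0
    sx <- bx - ax; sy <- by - ay
    den <- rx * sy - ry * sx
    ok <- abs(den) > 1e-300
    t <- ((ax - x0) * sy - (ay - y0) * sx) / den
    u <- ((ax - x0) * ry - (ay - y0) * rx) / den
    hit <- ok & t > 1e-12 & t <= 1 + 1e-12 & u >= -1e-12 & u <= 1 + 1e-12
    upd <- hit & t < tmin
    tmin[upd] <- t[upd]
    ei[upd] <- i
    j <- i
  }
  out <- cbind(rep(NA_real_, n), rep(NA_real_, n))
  hit <- !is.na(ei)
  if (any(hit)) {
    ii <- ei[hit]
    jj <- ifelse(ii == 1L, nv, ii - 1L)
    out[hit, ] <- reflect_across_edge(x1[hit], y1[hit],
                                      polygon[jj, 1L], polygon[jj, 2L],
                                      polygon[ii, 1L], polygon[ii, 2L])
  }
  out
}

# Vectorized core of resolve_step.  Inputs are the start/proposal coordinates,
# the geometry, the pre-move sub-region index, and a logical marking molecules
# whose crossing attempts must always be rejected (bound molecules tethered to
# their trapping region).  Returns list(x, y, crossed, region).
#
# Order of operations (documented contract):
#   1. proposals leaving the cell outline are specularly reflected at the
#      first intersected outline edge; if still outside, the move is cancelled;
#   2. a change of sub-region membership between start and (possibly
#      reflected) endpoint is an attempted border crossing, accepted with the
#      border region's P_crossing, else the move is cancelled (molecule stays
#      at p0).  One crossing test per step.
resolve_steps <- function(x0, y0, x1, y1, g, reg0 = NULL, confined = NULL) {
  n <- length(x0)
  outline <- g$cell_outline$polygon
  if (!all(point_in_polygon(x0, y0, outline)))
    stop("resolve_step: start position outside the cell outline")
  if (is.null(reg0)) reg0 <- region_index(x0, y0, g)
  if (is.null(confined)) confined <- logical(n)

  inside <- point_in_polygon(x1, y1, outline)
  if (!all(inside)) {
    esc <- which(!inside)
    refl <- reflect_at_outline(x0[esc], y0[esc], x1[esc], y1[esc], outline)
    ok <- !is.na(refl[, 1L]) &
      point_in_polygon(refl[, 1L], refl[, 2L], outline)
    x1[esc] <- ifelse(ok, refl[, 1L], x0[esc])
    y1[esc] <- ifelse(ok, refl[, 2L], y0[esc])
  }

  reg1 <- region_index(x1, y1, g)
  attempt <- reg1 != reg0
  crossed <- logical(n)
  if (any(attempt)) {
    att <- which(attempt)
    # border region: the sub-region being left, or entered when coming from
    # the outside pool
    border <- ifelse(reg0[att] != 0L, reg0[att], reg1[att])
    pcross <- vapply(g$sub_regions[border], `[[`, numeric(1), "P_crossing")
    acc <- stats::runif(length(att)) < pcross
    acc[confined[att]] <- FALSE
    rej <- att[!acc]
    x1[rej] <- x0[rej]; y1[rej] <- y0[rej]
    reg1[rej] <- reg0[rej]
    crossed[att[acc]] <- TRUE
  }
  list(x = x1, y = y1, crossed = crossed, region = reg1)
}

#' Resolve one Brownian step against the geometry
#'
#' A proposed move that exits the cell outline is specularly reflected at the
#' first intersected outline edge (cancelled if the reflection is still
#' outside, e.g. in sharp corners); a move that changes sub-region membership
#' is an attempted border crossing accepted with that border's `P_crossing`,
#' otherwise the molecule stays at `p0`.
#'
#' @param p0 Start position `c(x, y)` in um, inside the cell outline.
#' @param p1 Proposed position.
#' @param g `smf_geometry`.
#' @return List with `position` (final `c(x, y)`) and `crossing_event`
#'   (logical: a border crossing was attempted and accepted).
#' @export
resolve_step <- function(p0, p1, g) {
  stopifnot(inherits(g, "smf_geometry"))
  r <- resolve_steps(p0[1L], p0[2L], p1[1L], p1[2L], g)
  list(position = c(r$x, r$y), crossing_event = r$crossed)
}
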