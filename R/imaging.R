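# Image formation: pixel-integrated Gaussian PSF, Poisson shot noise and
# Gaussian readout noise around the camera offset; localization-based
# super-resolved maps with a configurable localization precision.

#' Gaussian point-spread-function model
#'
#' `sigma` is the configured quantity everywhere in the engine; the FWHM
#' (`2 * sqrt(2 * log(2)) * sigma`) is derived display metadata only.
#'
#' @param sigma PSF standard deviation, um.
#' @return List of class `smf_psf` with `sigma` and derived `fwhm`.
#' @export
psf_model <- function(sigma) {
  stopifnot(sigma > 0)
  structure(list(sigma = sigma, fwhm = 2 * sqrt(2 * log(2)) * sigma),
            class = "smf_psf")
}

#' Camera model
#'
#' @param offset Baseline level added to every pixel, ADU.
#' @param readout_sigma Gaussian readout noise standard deviation, ADU.
#' @param gain ADU per photon.
#' @param pixel_size Micrometers per camera pixel.
#' @return List of class `smf_camera`.
#' @details Defaults are EMCCD-plausible placeholders (offset 100 ADU,
#'   readout 5 ADU, unit gain); real systems should be configured explicitly.
#' @export
camera_model <- function(offset = 100, readout_sigma = 5, gain = 1,
                         pixel_size = 0.16) {
  stopifnot(gain > 0, readout_sigma >= 0, pixel_size > 0)
  structure(list(offset = offset, readout_sigma = readout_sigma, gain = gain,
                 pixel_size = pixel_size),
            class = "smf_camera")
}

#' Render one camera frame from emitting molecules
#'
#' The expected photon image is the sum over molecules of
#' `photons_per_frame` times a 2D Gaussian integrated with the error function
#' over each pixel (flux-conserving), truncated at 5 sigma (truncation error
#' below 1e-5).  Unless `noiseless`, each pixel then receives a Poisson draw
#' on its expected photons, is multiplied by the gain, and gets the offset
#' plus Gaussian readout noise.
#'
#' @param on_positions n x 2 matrix of emitting-molecule positions, um
#'   (positions outside the frame are clipped naturally).
#' @param psf `smf_psf`.
#' @param photons_per_frame Expected photons per molecule per frame; a vector
#'   gives per-molecule expectations (e.g. beam-weighted).
#' @param cam `smf_camera`.
#' @param shape Image dimensions `c(n_rows, n_cols)` = `c(ny, nx)` pixels;
#'   row = y, column = x.
#' @param noiseless If `TRUE`, return the expected image in ADU
#'   (`offset + gain * expected photons`) without any noise.
#' @return Numeric matrix `shape[1] x shape[2]` in ADU.
#' @export
render_frame <- function(on_positions, psf, photons_per_frame, cam, shape,
                         noiseless = FALSE) {
  stopifnot(all(shape >= 1))
  ny <- shape[1L]; nx <- shape[2L]
  s <- cam$pixel_size
  img <- matrix(0, ny, nx)
  if (!is.null(on_positions) && NROW(on_positions) > 0L) {
    pos <- rbind(on_positions)
    ph <- rep_len(photons_per_frame, nrow(pos))
    half <- 5 * psf$sigma
    for (m in seq_len(nrow(pos))) {
      x <- pos[m, 1L]; y <- pos[m, 2L]
      i0 <- max(floor((x - half) / s), 0); i1 <- min(ceiling((x + half) / s) - 1, nx - 1)
      j0 <- max(floor((y - half) / s), 0); j1 <- min(ceiling((y + half) / s) - 1, ny - 1)
      if (i0 > i1 || j0 > j1) next
      ii <- i0:i1; jj <- j0:j1
      px <- stats::pnorm((ii + 1) * s, x, psf$sigma) - stats::pnorm(ii * s, x, psf$sigma)
      py <- stats::pnorm((jj + 1) * s, y, psf$sigma) - stats::pnorm(jj * s, y, psf$sigma)
      img[jj + 1L, ii + 1L] <- img[jj + 1L, ii + 1L] + ph[m] * outer(py, px)
    }
  }
  if (noiseless) return(cam$offset + cam$gain * img)
  shot <- matrix(stats::rpois(length(img), img), ny, nx)
  cam$offset + cam$gain * shot +
    matrix(stats::rnorm(length(img), 0, cam$readout_sigma), ny, nx)
}

#' Turn emitting molecules into sub-pixel localizations
#'
#' One detection per ON molecule per frame, at the true position plus
#' independent per-axis Gaussian jitter of standard deviation `loc_sigma`,
#' standing in for the localization error of a fitting-based localizer.
#'
#' @param on_molecules n x 2 matrix of true positions, um; row names or the
#'   `ids` argument identify the source molecules.
#' @param loc_sigma Localization precision (per-axis sd), um.
#' @param frame Frame index attached to the detections.
#' @param ids Optional integer molecule ids (default `1:n`).
#' @return `data.frame(frame, x, y, source_molecule)`.
#' @export
localize_detections <- function(on_molecules, loc_sigma, frame = 1L,
                                ids = NULL) {
  stopifnot(loc_sigma >= 0)
  pos <- rbind(on_molecules)
  n <- nrow(pos)
  if (n == 0L)
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      source_molecule = integer(0)))
  if (is.null(ids)) ids <- seq_len(n)
  data.frame(frame = rep_len(as.integer(frame), n),
             x = pos[, 1L] + stats::rnorm(n, 0, loc_sigma),
             y = pos[, 2L] + stats::rnorm(n, 0, loc_sigma),
             source_molecule = as.integer(ids))
}

#' Accumulate detections into a super-resolved map
#'
#' Integer 2D histogram of detections on a super-resolution grid: one
#' detection contributes intensity 1 to the pixel containing it (half-open
#' pixel convention `[i*s, (i+1)*s)`), so the map total equals the number of
#' in-frame detections.
#'
#' @param detections `data.frame` with `x`, `y` in um (as produced by
#'   [localize_detections()]).
#' @param sr_pixel Super-resolution pixel size, um (conventionally 0.032).
#' @param shape Map dimensions `c(n_rows, n_cols)`.
#' @return Integer matrix.
#' @export
accumulate_sr_map <- function(detections, sr_pixel, shape) {
  stopifnot(sr_pixel > 0, all(shape >= 1))
  ny <- shape[1L]; nx <- shape[2L]
  i <- floor(detections$x / sr_pixel)   # column, 0-based
  j <- floor(detections$y / sr_pixel)   # row, 0-based
  keep <- i >= 0 & i < nx & j >= 0 & j < ny
  idx <- j[keep] + 1L + i[keep] * ny
  matrix(tabulate(idx, nbins = ny * nx), ny, nx)
}

#' Gaussian illumination weight of a parked laser beam
#'
#' `exp(-|p - center|^2 / (2 * sigma_beam^2))`; multiplies the molecular
#' photon rate in FCS rendering.
#'
#' @param p Position `c(x, y)` or n x 2 matrix, um.
#' @param center Beam center, um.
#' @param sigma_beam Beam profile standard deviation, um.
#' @return Weight(s) in (0, 1].
#' @export
gaussian_beam_weight <- function(p, center, sigma_beam) {
  stopifnot(sigma_beam > 0)
  p <- rbind(p)
  d2 <- (p[, 1L] - center[1L])^2 + (p[, 2L] - center[2L])^2
  unname(exp(-d2 / (2 * sigma_beam^2)))
}
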