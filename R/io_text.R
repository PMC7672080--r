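# Text exchange formats: .trc trajectory tables, tab-separated curve files,
# and the structured run configuration.

#' Write trajectories as a .trc table
#'
#' Five whitespace-separated columns, one row per localization: trajectory
#' index (1-based), frame index (1-based), x and y in pixels
#' (um / pixel_size, 6 decimals), and an intensity column.  Rows are sorted
#' by trajectory then frame.
#'
#' @param trajs List of trajectories (`data.frame(frame, x, y)` in um).
#' @param path Output path.
#' @param pixel_size Micrometers per pixel used for the unit conversion.
#' @param intensity Intensity value(s) written in the last column.
#' @return `path`, invisibly.
#' @export
write_trc <- function(trajs, path, pixel_size = 0.16, intensity = 1) {
  rows <- lapply(seq_along(trajs), function(i) {
    d <- trajs[[i]]
    data.frame(traj = i, frame = d$frame, x = d$x / pixel_size,
               y = d$y / pixel_size, intensity = rep_len(intensity, nrow(d)))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(traj = integer(0), frame = integer(0),
                                      x = numeric(0), y = numeric(0),
                                      intensity = numeric(0))
  tab <- tab[order(tab$traj, tab$frame), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d\t%d\t%.6f\t%.6f\t%.6f", tab$traj, tab$frame,
                     tab$x, tab$y, tab$intensity), con)
  invisible(path)
}

#' Read a .trc trajectory table
#'
#' @param path File written by [write_trc()] (or any 5-column .trc dialect
#'   with the same layout).
#' @param pixel_size Micrometers per pixel; positions are converted back to
#'   um.
#' @return List of trajectories (`data.frame(frame, x, y)` in um, plus the
#'   `intensity` column).
#' @export
read_trc <- function(path, pixel_size = 0.16) {
  tab <- utils::read.table(path, col.names = c("traj", "frame", "x", "y",
                                               "intensity"))
  if (nrow(tab) == 0L) return(list())
  out <- lapply(split(tab, tab$traj), function(d) {
    data.frame(frame = d$frame, x = d$x * pixel_size, y = d$y * pixel_size,
               intensity = d$intensity)
  })
  names(out) <- NULL
  out
}

#' Write labeled curves as tab-separated text
#'
#' Header row, a `time` column in seconds, locale-independent decimal
#' points, 6-decimal fixed precision.
#'
#' @param curves `data.frame` whose first column is `time`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  stopifnot(is.data.frame(curves), names(curves)[1L] == "time")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(curves), collapse = "\t"), con)
  if (nrow(curves) > 0L) {
    fmt <- do.call(cbind, lapply(curves, function(v) sprintf("%.6f", v)))
    writeLines(apply(fmt, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a tab-separated curve file
#' @param path File written by [write_curves()].
#' @return `data.frame` with the original columns.
#' @export
read_curves <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

# --- run configuration -----------------------------------------------------

default_config <- function() {
  list(
    modality = "spt",
    geometry = list(fixture = list(cell_um = c(30, 20),
                                   contact_center_um = c(8, 10),
                                   contact_radius_um = 3)),
    pixel_size_um = 0.16,
    n_molecules = 250,
    dt_ms = 20,
    n_frames = 1000,
    D_out_um2_per_s = 0.3,
    D_in_um2_per_s = 0.3,
    D_trap_um2_per_s = 0.04,
    k_on_per_s = 0.15,
    k_off_per_s = 0.015,
    P_crossing = 0.3,
    k_on_fluo_per_s = 1,
    k_off_fluo_per_s = 3,
    k_bleach_per_s = 4.25,
    k_activ_per_s = 1,
    photons_per_frame = 500,
    psf_sigma_um = 0.17,
    loc_sigma_um = 0.025,
    sr_pixel_um = 0.032,
    fcs_sigma_um = 0.25,
    fcs_aperture_um = 1,
    fcs_sample_rate_hz = 500,
    roi_centers_um = list(c(20, 6), c(20, 14)),
    roi_diameter_um = 2.8
  )
}

# Validated envelopes: values outside warn (the engine still runs), values
# that are structurally impossible error with a field-level message.
validate_config <- function(cfg) {
  num_fields <- c("pixel_size_um", "n_molecules", "dt_ms", "n_frames",
                  "D_out_um2_per_s", "D_in_um2_per_s", "D_trap_um2_per_s",
                  "k_on_per_s", "k_off_per_s", "P_crossing",
                  "k_on_fluo_per_s", "k_off_fluo_per_s", "k_bleach_per_s",
                  "k_activ_per_s", "photons_per_frame", "psf_sigma_um",
                  "loc_sigma_um", "sr_pixel_um")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v))
      stop("config field '", f, "' must be a single number")
    if (v < 0) stop("config field '", f, "' must be >= 0")
  }
  if (cfg$P_crossing > 1) stop("config field 'P_crossing' must be <= 1")
  if (cfg$pixel_size_um <= 0) stop("config field 'pixel_size_um' must be > 0")
  if (cfg$dt_ms < 2 || cfg$dt_ms > 100)
    warning("dt_ms = ", cfg$dt_ms, " outside the validated 2-100 ms envelope")
  if (cfg$n_frames > 100000)
    warning("n_frames exceeds the validated 100,000-frame envelope")
  if (cfg$n_molecules > 150000)
    warning("n_molecules exceeds the validated 150,000 envelope")
  invisible(cfg)
}

#' Read a run configuration
#'
#' The configuration is a single JSON file with units embedded in the key
#' names (e.g. `dt_ms`, `D_out_um2_per_s`); missing keys take the
#' documented defaults, unknown keys error.
#'
#' @param path JSON file.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  unknown <- setdiff(names(cfg), c(names(base), "seed", "comment"))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  base[names(cfg)] <- cfg
  validate_config(base)
  base
}

#' Write a run configuration
#' @param cfg Config list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

config_geometry <- function(cfg) {
  gsrc <- cfg$geometry
  if (!is.null(gsrc$fixture)) {
    fx <- gsrc$fixture
    contact <- if (!is.null(fx$contact_center_um))
      list(center = unlist(fx$contact_center_um),
           radius = fx$contact_radius_um)
    make_fixture_geometry(cell = unlist(fx$cell_um), contact = contact,
                          D_out = cfg$D_out_um2_per_s,
                          D_in = cfg$D_in_um2_per_s,
                          D_trap = cfg$D_trap_um2_per_s,
                          k_on = cfg$k_on_per_s, k_off = cfg$k_off_per_s,
                          P_crossing = cfg$P_crossing,
                          pixel_size = cfg$pixel_size_um)
  } else if (!is.null(gsrc$file)) {
    load_regions(unlist(gsrc$file),
                 dialect = if (is.null(gsrc$dialect)) "polygon_text" else gsrc$dialect,
                 pixel_size = cfg$pixel_size_um,
                 D_out = cfg$D_out_um2_per_s, D_in = cfg$D_in_um2_per_s,
                 D_trap = cfg$D_trap_um2_per_s, k_on = cfg$k_on_per_s,
                 k_off = cfg$k_off_per_s, P_crossing = cfg$P_crossing)
  } else stop("config field 'geometry' needs either 'fixture' or 'file'")
}
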