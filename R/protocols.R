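# Acquisition protocols: the five imaging modalities as timed schedules
# combining motion, photophysics and imaging, plus CNN training-pair
# generation and fixture geometries.

circle_polygon <- function(center, radius, n_vertices = 64L) {
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
}

#' Build a rectangular two-region fixture geometry
#'
#' Stands in for microscopy-derived cell outlines in tests and examples: a
#' rectangular cell with an optional circular or strip-shaped adhesive
#' contact, pre-filled with the canonical membrane-dynamics defaults
#' (D_out = 0.3, D_in = 0.3, D_trap = 0.04 um^2/s; k_on = 0.15,
#' k_off = 0.015 1/s; P_crossing = 0.3).
#'
#' @param cell `c(width, height)` of the cell rectangle, um (origin corner).
#' @param contact `list(center = c(x, y), radius = r)` for a circular
#'   contact (polygonized with `n_vertices` vertices),
#'   `list(strip = c(x0, x1))` for a vertical strip spanning the cell
#'   height, or `NULL` for a single uniform region.
#' @param D_out,D_in,D_trap Diffusion coefficients, um^2/s.
#' @param k_on,k_off Trapping kinetics inside the contact, 1/s.
#' @param P_crossing Border crossing probability of the contact.
#' @param pixel_size Reference pixel size, um.
#' @param n_vertices Vertices of the polygonized circle.
#' @return `smf_geometry`.
#' @export
make_fixture_geometry <- function(cell = c(30, 20),
                                  contact = list(center = c(8, 10), radius = 3),
                                  D_out = 0.3, D_in = 0.3, D_trap = 0.04,
                                  k_on = 0.15, k_off = 0.015, P_crossing = 0.3,
                                  pixel_size = 0.16, n_vertices = 64L) {
  outline <- region("cell", rbind(c(0, 0), c(cell[1L], 0), cell,
                                  c(0, cell[2L])),
                    kind = "cell_outline", D_free = D_out)
  subs <- list()
  if (!is.null(contact)) {
    poly <- if (!is.null(contact$strip)) {
      s <- contact$strip
      rbind(c(s[1L], 0), c(s[2L], 0), c(s[2L], cell[2L]), c(s[1L], cell[2L]))
    } else {
      circle_polygon(contact$center, contact$radius,
                     if (is.null(contact$n_vertices)) n_vertices else contact$n_vertices)
    }
    subs <- list(region("contact", poly, kind = "contact", D_free = D_in,
                        D_trap = D_trap, k_on = k_on, k_off = k_off,
                        P_crossing = P_crossing))
  }
  geometry(outline, subs, pixel_size = pixel_size)
}

#' Define a laser pulse with a circular region of interest
#'
#' The pulse is spatially uniform (top-hat) inside the circle: the stated
#' experiments specify only spot diameters, and the top-hat is the simplest
#' model consistent with selective bleaching/activation of circular areas.
#'
#' @param kind `"bleach"` or `"activation"`.
#' @param center Circle center `c(x, y)`, um.
#' @param diameter Circle diameter, um (conventional spot: 2.8 um).
#' @param t_start Pulse onset, s.
#' @param duration Pulse duration, s.
#' @param rate Bleaching/activation rate while active, 1/s.
#' @return List of class `smf_pulse`.
#' @export
pulse <- function(kind = c("bleach", "activation"), center, diameter = 2.8,
                  t_start, duration, rate) {
  kind <- match.arg(kind)
  stopifnot(diameter > 0, duration > 0, rate >= 0)
  structure(list(kind = kind, center = center, radius = diameter / 2,
                 t_start = t_start, duration = duration, rate = rate),
            class = "smf_pulse")
}

in_circle <- function(x, y, center, radius) {
  (x - center[1L])^2 + (y - center[2L])^2 <= radius^2
}

check_roi_in_cell <- function(center, radius, g, what = "ROI") {
  th <- 2 * pi * (0:15) / 16
  bx <- center[1L] + radius * cos(th)
  by <- center[2L] + radius * sin(th)
  ok <- all(point_in_polygon(bx, by, g$cell_outline$polygon)) &&
    all(point_in_polygon(center[1L], center[2L], g$cell_outline$polygon))
  if (!ok) stop(what, " at (", center[1L], ", ", center[2L],
                ") is not inside the cell outline")
  invisible(TRUE)
}

# Recovery/decay frame schedule with decreasing frame rate: 2 Hz for 10 s,
# 0.5 Hz for 20 s, 0.1 Hz for 50 s (offsets from the pulse end; 0 is the
# first post-pulse frame).
decreasing_rate_schedule <- function() {
  c(0, seq(0.5, 10, by = 0.5), seq(12, 30, by = 2), seq(40, 80, by = 10))
}

#' FRAP acquisition protocol
#'
#' Default schedule: 10 s baseline at 1 Hz, a 400 ms bleach pulse at
#' 4.25 1/s in 2.8 um circles, then 80 s of recovery sampled at a
#' decreasing frame rate (2 -> 0.1 Hz).  The engine advances with fixed
#' `dt`; frames are sampled at the scheduled times.
#'
#' @param roi_centers Matrix (k x 2) or list of bleach-spot centers, um.
#' @param bleach_rate Bleaching rate during the pulse, 1/s.
#' @param bleach_duration Pulse duration, s.
#' @param diameter Spot diameter, um.
#' @param baseline_duration Baseline length, s, sampled at `baseline_rate`.
#' @param baseline_rate Baseline frame rate, Hz.
#' @param recovery_offsets Frame times after the pulse end, s.
#' @param dt Engine time step, s.
#' @return List of class `smf_protocol`.
#' @export
frap_protocol <- function(roi_centers, bleach_rate = 4.25,
                          bleach_duration = 0.4, diameter = 2.8,
                          baseline_duration = 10, baseline_rate = 1,
                          recovery_offsets = decreasing_rate_schedule(),
                          dt = 0.02) {
  roi_centers <- rbind_centers(roi_centers)
  t_bleach <- baseline_duration
  pulses <- lapply(seq_len(nrow(roi_centers)), function(i)
    pulse("bleach", roi_centers[i, ], diameter, t_bleach, bleach_duration,
          bleach_rate))
  frame_times <- c(seq(0, baseline_duration - 1 / baseline_rate,
                       by = 1 / baseline_rate),
                   t_bleach + bleach_duration + recovery_offsets)
  structure(list(modality = "FRAP", dt = dt, frame_times = frame_times,
                 pulses = pulses, roi_centers = roi_centers,
                 roi_radius = diameter / 2,
                 t_pulse_start = t_bleach,
                 t_pulse_end = t_bleach + bleach_duration),
            class = "smf_protocol")
}

#' PAF acquisition protocol
#'
#' Default schedule: 12 s baseline at ~0.3 Hz, a 300 ms photo-activation
#' pulse at 1 1/s in 2.8 um circles, then 80 s of decay sampled at a
#' decreasing frame rate.
#'
#' @param roi_centers Matrix (k x 2) or list of activation-spot centers, um.
#' @param activation_rate Activation rate during the pulse, 1/s.
#' @param activation_duration Pulse duration, s.
#' @param diameter Spot diameter, um.
#' @param baseline_duration,baseline_rate Baseline sampling.
#' @param decay_offsets Frame times after the pulse end, s.
#' @param dt Engine time step, s.
#' @return List of class `smf_protocol`.
#' @export
paf_protocol <- function(roi_centers, activation_rate = 1,
                         activation_duration = 0.3, diameter = 2.8,
                         baseline_duration = 12, baseline_rate = 0.3,
                         decay_offsets = decreasing_rate_schedule(),
                         dt = 0.02) {
  roi_centers <- rbind_centers(roi_centers)
  t0 <- baseline_duration
  pulses <- lapply(seq_len(nrow(roi_centers)), function(i)
    pulse("activation", roi_centers[i, ], diameter, t0, activation_duration,
          activation_rate))
  frame_times <- c(seq(0, baseline_duration - 1 / baseline_rate,
                       by = 1 / baseline_rate),
                   t0 + activation_duration + decay_offsets)
  structure(list(modality = "PAF", dt = dt, frame_times = frame_times,
                 pulses = pulses, roi_centers = roi_centers,
                 roi_radius = diameter / 2,
                 t_pulse_start = t0, t_pulse_end = t0 + activation_duration),
            class = "smf_protocol")
}

rbind_centers <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  rbind(x)
}

# Shared FRAP/PAF engine: fixed-dt stepping, pulse gating, ROI counts at
# scheduled frame times.  Intensity = number of ON molecules inside each ROI
# circle (analytic measurement; PSF rendering adds nothing to curve shape at
# these densities and is available through render_frame for image export).
run_pulse_protocol <- function(g, n_molecules, params, protocol, seed,
                               init, warmup_steps, initial_fluor) {
  stopifnot(inherits(g, "smf_geometry"), inherits(protocol, "smf_protocol"))
  for (p in protocol$pulses)
    check_roi_in_cell(p$center, p$radius, g, paste0(p$kind, " ROI"))
  streams <- rng_streams(seed)
  dt <- protocol$dt
  frame_steps <- round(protocol$frame_times / dt)
  n_steps <- max(frame_steps)
  k <- nrow(protocol$roi_centers)
  curves <- matrix(NA_real_, length(frame_steps), k)

  mols <- with_stream(streams, "motion",
    initialize_positions(n_molecules, g, mode = init,
                         warmup_steps = warmup_steps, dt = dt))
  mols$fluor <- rep(as.integer(initial_fluor), n_molecules)

  record <- function(i) {
    hit <- which(frame_steps == i)
    if (length(hit)) {
      on <- mols$fluor == fluor_codes[["ON"]]
      for (r in seq_len(k))
        curves[hit, r] <<- sum(on & in_circle(mols$x, mols$y,
                                              protocol$roi_centers[r, ],
                                              protocol$roi_radius))
    }
  }
  record(0L)
  fp <- fluor_params(k_on_fluo = params$k_on_fluo,
                     k_off_fluo = params$k_off_fluo,
                     k_bleach = 0, k_activ = 0,
                     photons_per_frame = params$photons_per_frame)
  for (i in seq_len(n_steps)) {
    t0 <- (i - 1) * dt
    bleach <- activ <- rep(FALSE, n_molecules)
    any_pulse <- FALSE
    for (p in protocol$pulses) {
      if (t0 >= p$t_start - 1e-9 && t0 < p$t_start + p$duration - 1e-9) {
        cov <- in_circle(mols$x, mols$y, p$center, p$radius)
        if (p$kind == "bleach") bleach <- bleach | cov else activ <- activ | cov
        any_pulse <- TRUE
        fp$k_bleach <- if (p$kind == "bleach") p$rate else fp$k_bleach
        fp$k_activ <- if (p$kind == "activation") p$rate else fp$k_activ
      }
    }
    needs_fluor <- any_pulse || params$k_off_fluo > 0 ||
      any(mols$fluor == fluor_codes[["OFF"]])
    if (needs_fluor)
      mols$fluor <- with_stream(streams, "photo",
        update_fluor(mols$fluor, fp, dt, bleach, activ))
    mols <- with_stream(streams, "motion", step_all(mols, g, dt))
    record(i)
  }
  colnames(curves) <- paste0("roi_", seq_len(k))
  list(time = protocol$frame_times, curves = curves, protocol = protocol,
       molecules = mols)
}

#' Run a FRAP simulation
#'
#' Baseline frames, a top-hat bleach pulse (bleaching active only inside the
#' circular ROIs and only during the pulse), then recovery frames at the
#' protocol's variable frame schedule.  Returns raw per-ROI intensity curves
#' (ON-molecule counts inside each ROI); normalization is a separate
#' analysis step ([normalize_frap()]).
#'
#' @param g `smf_geometry`.
#' @param n_molecules Number of molecules.
#' @param params `smf_fluor_params`; FRAP defaults to a non-blinking
#'   fluorophore (`k_on_fluo = 1`, `k_off_fluo = 0`), i.e. all molecules
#'   start ON, as for a conventional fluorescent protein tag.
#' @param protocol `smf_protocol` from [frap_protocol()].
#' @param seed Optional integer root seed (split into subsystem streams).
#' @param init `"uniform"` or `"equilibrated"` initial placement.
#' @param warmup_steps Warm-up steps for equilibrated placement.
#' @return List with `time`, `curves` (frames x ROIs), `protocol`,
#'   final `molecules`.
#' @export
run_frap <- function(g, n_molecules,
                     params = fluor_params(k_on_fluo = 1, k_off_fluo = 0),
                     protocol, seed = NULL,
                     init = c("uniform", "equilibrated"), warmup_steps = 0L) {
  init <- match.arg(init)
  if (protocol$modality != "FRAP") stop("protocol modality must be FRAP")
  run_pulse_protocol(g, n_molecules, params, protocol, seed, init,
                     warmup_steps, fluor_codes[["ON"]])
}

#' Run a PAF simulation
#'
#' All molecules start photoactivatable-dark (PREACTIVE); the activation
#' pulse converts them to switchable dark only inside the ROI during the
#' pulse, after which they switch on at `k_on_fluo`.  The ROI intensity is
#' recorded over the decay phase; PAF is the mirror of FRAP.
#'
#' @inheritParams run_frap
#' @param params `smf_fluor_params`; PAF default uses a fast
#'   `k_on_fluo = 10` (activated tags become fluorescent within ~0.1 s) and
#'   no blinking.
#' @param protocol `smf_protocol` from [paf_protocol()].
#' @return As [run_frap()].
#' @export
run_paf <- function(g, n_molecules,
                    params = fluor_params(k_on_fluo = 10, k_off_fluo = 0),
                    protocol, seed = NULL,
                    init = c("uniform", "equilibrated"), warmup_steps = 0L) {
  init <- match.arg(init)
  if (protocol$modality != "PAF") stop("protocol modality must be PAF")
  run_pulse_protocol(g, n_molecules, params, protocol, seed, init,
                     warmup_steps, fluor_codes[["PREACTIVE"]])
}

#' Run an SPT (uPAINT-like) simulation
#'
#' Per frame: molecules move ([step_all()]), fluorophores blink
#' (event-based), and the positions of emitting molecules are recorded with
#' localization jitter.  A trajectory is the maximal run of consecutive
#' frames during which a molecule stays ON.
#'
#' @param g `smf_geometry`.
#' @param n_molecules Sparse labeled-molecule count (canonical SPT run: 250).
#' @param params `smf_fluor_params`; SPT defaults `k_on_fluo = 1`,
#'   `k_off_fluo = 3` 1/s give the short trajectory durations typical of
#'   uPAINT.
#' @param n_frames Frames to acquire (canonical: 4000 at 50 Hz).
#' @param dt Frame interval, s.
#' @param loc_sigma Localization precision (per-axis sd), um.
#' @param seed Optional root seed.
#' @param init,warmup_steps Initial placement (see [initialize_positions()]).
#' @param render If `TRUE`, also return a camera image stack of the emitting
#'   molecules (one frame per acquisition frame), rendered with `psf`/`cam`.
#' @param psf,cam PSF and camera models used when `render = TRUE`.
#' @return List with `trajectories` (list of `data.frame(frame, x, y)`),
#'   `detections` (all localizations with molecule ids), `n_frames`, `dt`,
#'   and `stack` (list of matrices, or `NULL` unless `render`).
#' @export
run_spt <- function(g, n_molecules = 250L, params = fluor_params(),
                    n_frames = 4000L, dt = 0.02, loc_sigma = 0.025,
                    seed = NULL, init = c("uniform", "equilibrated"),
                    warmup_steps = 0L, render = FALSE,
                    psf = psf_model(0.22), cam = camera_model()) {
  init <- match.arg(init)
  streams <- rng_streams(seed)
  duration <- n_frames * dt

  bursts <- with_stream(streams, "photo",
    blink_bursts(n_molecules, params$k_on_fluo, params$k_off_fluo, duration,
                 initial = "equilibrium"))
  on_mat <- matrix(FALSE, n_molecules, n_frames)
  if (nrow(bursts)) {
    bf <- burst_frames(bursts$t_on, bursts$t_off, dt, n_frames, "midpoint")
    keep <- bf$count > 0
    if (any(keep)) {
      fr <- sequence(bf$count[keep], from = bf$first[keep] + 1L, by = 1L)
      ml <- rep(bursts$mol[keep], bf$count[keep])
      on_mat[cbind(ml, fr)] <- TRUE
    }
  }

  mols <- with_stream(streams, "motion",
    initialize_positions(n_molecules, g, mode = init,
                         warmup_steps = warmup_steps, dt = dt))
  recs <- vector("list", n_frames)
  with_stream(streams, "motion", {
    for (f in seq_len(n_frames)) {
      on <- on_mat[, f]
      if (any(on))
        recs[[f]] <- cbind(mol = which(on), frame = f,
                           x = mols$x[on], y = mols$y[on])
      if (f < n_frames) mols <- step_all(mols, g, dt)
    }
  })
  det <- as.data.frame(do.call(rbind, recs))
  if (is.null(det) || nrow(det) == 0L)
    return(list(trajectories = list(),
                detections = data.frame(mol = integer(0), frame = integer(0),
                                        x = numeric(0), y = numeric(0)),
                n_frames = n_frames, dt = dt))
  det <- det[order(det$mol, det$frame), ]
  if (loc_sigma > 0) {
    jit <- with_stream(streams, "imaging",
                       stats::rnorm(2L * nrow(det), 0, loc_sigma))
    det$x <- det$x + jit[seq_len(nrow(det))]
    det$y <- det$y + jit[nrow(det) + seq_len(nrow(det))]
  }
  seg <- cumsum(c(TRUE, diff(det$frame) != 1L | diff(det$mol) != 0L))
  trajs <- lapply(split(det[c("frame", "x", "y")], seg), function(d) {
    rownames(d) <- NULL
    d
  })
  names(trajs) <- NULL
  stack <- NULL
  if (render) {
    bbox <- apply(g$cell_outline$polygon, 2L, max)
    shape <- c(ceiling(bbox[2L] / cam$pixel_size),
               ceiling(bbox[1L] / cam$pixel_size))
    stack <- with_stream(streams, "imaging",
      lapply(seq_len(n_frames), function(f) {
        on <- det$frame == f
        render_frame(cbind(det$x[on], det$y[on]), psf,
                     params$photons_per_frame, cam, shape)
      }))
  }
  list(trajectories = trajs, detections = det, n_frames = n_frames, dt = dt,
       stack = stack)
}

#' Run a dSTORM/PALM simulation of immobile molecules
#'
#' Event-based photophysics (all fluorophores start dark, as after pumping
#' dyes into a non-emitting state) over the full acquisition; each frame a
#' molecule is ON for at least half the frame yields one detection at the
#' true position plus localization jitter, and detections are accumulated
#' into a super-resolved map.
#'
#' @param g `smf_geometry`; diffusion coefficients should be 0 (cell
#'   fixation) -- nonzero values produce a warning and are ignored
#'   (molecules stay immobile).
#' @param n_molecules Number of labeled molecules (canonical: 70,000).
#' @param params `smf_fluor_params`; canonical dSTORM blinking rates are
#'   `k_on_fluo = 0.006`, `k_off_fluo = 9.3` 1/s.
#' @param n_frames Frames (canonical: 80,000 at 20 ms).
#' @param dt Frame interval, s.
#' @param loc_sigma Localization precision, um (canonical 0.025).
#' @param sr_pixel Super-resolution map pixel, um (canonical 0.032).
#' @param seed Optional root seed.
#' @param mode `"full"` returns detections and the super-resolved map;
#'   `"count"` skips both and reports only detection totals (fast path for
#'   large acquisitions).
#' @return List with `n_detections`, `expected_detections` (closed-form
#'   occupancy expectation), and for `mode = "full"` also `detections` and
#'   `sr_map`.
#' @export
run_storm <- function(g, n_molecules = 70000L,
                      params = fluor_params(k_on_fluo = 0.006, k_off_fluo = 9.3),
                      n_frames = 80000L, dt = 0.02, loc_sigma = 0.025,
                      sr_pixel = 0.032, seed = NULL,
                      mode = c("full", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "smf_geometry"))
  Dmax <- max(c(g$cell_outline$D_free,
                vapply(g$sub_regions, `[[`, numeric(1), "D_free")))
  if (Dmax > 0)
    warning("geometry carries nonzero diffusion coefficients; molecules are ",
            "kept immobile (set D = 0 to mimic fixation)")
  streams <- rng_streams(seed)
  duration <- n_frames * dt

  bursts <- with_stream(streams, "photo",
    blink_bursts(n_molecules, params$k_on_fluo, params$k_off_fluo, duration,
                 initial = "off"))
  bf <- burst_frames(bursts$t_on, bursts$t_off, dt, n_frames, "overlap")
  n_det <- sum(bf$count)
  kon <- params$k_on_fluo; koff <- params$k_off_fluo
  expected <- as.numeric(n_molecules) * n_frames * kon / (kon + koff)
  out <- list(n_detections = n_det, expected_detections = expected,
              n_molecules = n_molecules, n_frames = n_frames, dt = dt)
  if (mode == "count") return(out)

  mols <- with_stream(streams, "motion",
    initialize_positions(n_molecules, g, mode = "uniform"))
  keep <- bf$count > 0
  fr <- sequence(bf$count[keep], from = bf$first[keep] + 1L, by = 1L)
  ml <- rep(bursts$mol[keep], bf$count[keep])
  det <- with_stream(streams, "imaging",
    localize_detections(cbind(mols$x[ml], mols$y[ml]), loc_sigma,
                        frame = fr, ids = ml))
  bbox <- apply(g$cell_outline$polygon, 2L, max)
  shape <- c(ceiling(bbox[2L] / sr_pixel), ceiling(bbox[1L] / sr_pixel))
  out$detections <- det
  out$sr_map <- accumulate_sr_map(det, sr_pixel, shape)
  out
}

#' FCS beam and detection aperture
#'
#' @param center Beam center `c(x, y)`, um.
#' @param sigma_beam Gaussian beam profile sd, um (canonical 0.25).
#' @param aperture Side of the square detection area centered on the beam,
#'   um (canonical 1).
#' @param sample_rate Sampling rate, Hz (canonical 200 in contacts, 500 in
#'   free membrane).
#' @return List of class `smf_fcs_beam`.
#' @export
fcs_beam <- function(center, sigma_beam = 0.25, aperture = 1,
                     sample_rate = 500) {
  stopifnot(sigma_beam > 0, aperture > 0, sample_rate > 0)
  structure(list(center = center, sigma_beam = sigma_beam,
                 aperture = aperture, sample_rate = sample_rate),
            class = "smf_fcs_beam")
}

#' Run an FCS simulation
#'
#' A Gaussian laser beam parked at a fixed position; at each sample every ON
#' molecule inside the square detection aperture contributes
#' `photons_per_frame * gaussian_beam_weight()` to the integrated intensity.
#' Aperture integration is analytic (no pixel rendering), which does not
#' change the statistics of the fluctuation trace.
#'
#' @param g `smf_geometry`.
#' @param n_molecules Number of molecules (intermediate density).
#' @param params `smf_fluor_params`; default non-blinking so that the
#'   autocorrelation decay reports diffusion only.
#' @param beam `smf_fcs_beam`.
#' @param n_samples Number of samples (canonical envelope: 60,000).
#' @param seed Optional root seed.
#' @param observational_bleach_rate Optional slow ON -> BLEACHED rate (1/s)
#'   applied everywhere, modelling observational photobleaching (off by
#'   default).
#' @param cam Optional `smf_camera`: adds Poisson shot noise plus
#'   aperture-integrated offset and readout noise to the trace.
#' @param molecules Optional `smf_molecules` to start from (overrides the
#'   uniform placement; useful for controlled configurations).
#' @return `data.frame(t, intensity)`; attribute `"beam"` carries the setup.
#' @export
run_fcs <- function(g, n_molecules,
                    params = fluor_params(k_on_fluo = 1, k_off_fluo = 0),
                    beam, n_samples = 60000L, seed = NULL,
                    observational_bleach_rate = 0, cam = NULL,
                    molecules = NULL) {
  stopifnot(inherits(beam, "smf_fcs_beam"))
  if (!point_in_polygon(beam$center[1L], beam$center[2L],
                        g$cell_outline$polygon))
    stop("FCS beam center is not inside the cell outline")
  streams <- rng_streams(seed)
  dt <- 1 / beam$sample_rate
  half <- beam$aperture / 2

  mols <- if (!is.null(molecules)) {
    n_molecules <- nrow(molecules)
    molecules
  } else with_stream(streams, "motion",
    initialize_positions(n_molecules, g, mode = "uniform"))
  pon <- if (params$k_on_fluo + params$k_off_fluo > 0)
    params$k_on_fluo / (params$k_on_fluo + params$k_off_fluo) else 1
  mols$fluor <- with_stream(streams, "photo",
    as.integer(ifelse(stats::runif(n_molecules) < pon,
                      fluor_codes[["ON"]], fluor_codes[["OFF"]])))
  fp <- params
  fp$k_bleach <- observational_bleach_rate
  fluor_dynamic <- params$k_off_fluo > 0 || observational_bleach_rate > 0 ||
    any(mols$fluor == fluor_codes[["OFF"]])

  intensity <- numeric(n_samples)
  measure <- function() {
    on <- mols$fluor == fluor_codes[["ON"]] &
      abs(mols$x - beam$center[1L]) <= half &
      abs(mols$y - beam$center[2L]) <= half
    if (!any(on)) return(0)
    w <- gaussian_beam_weight(cbind(mols$x[on], mols$y[on]), beam$center,
                              beam$sigma_beam)
    params$photons_per_frame * sum(w)
  }
  with_stream(streams, "motion", {
    for (i in seq_len(n_samples)) {
      intensity[i] <- measure()
      if (fluor_dynamic)
        mols$fluor <- with_stream(streams, "photo",
          update_fluor(mols$fluor, fp, dt,
                       bleach_active = observational_bleach_rate > 0))
      if (i < n_samples) mols <- step_all(mols, g, dt)
    }
  })
  if (!is.null(cam)) {
    n_px <- (beam$aperture / cam$pixel_size)^2
    intensity <- with_stream(streams, "imaging",
      cam$gain * stats::rpois(n_samples, intensity) +
        n_px * cam$offset +
        stats::rnorm(n_samples, 0, sqrt(n_px) * cam$readout_sigma))
  }
  out <- data.frame(t = (seq_len(n_samples) - 1L) * dt, intensity = intensity)
  attr(out, "beam") <- beam
  out
}

#' Contact enrichment versus equilibration time
#'
#' Diagnostic for the slow build-up of molecular enrichment in a trapping
#' contact: starting from a uniform placement, the population is advanced
#' and the density ratio contact / free-pool is recorded at the requested
#' times.  The full trapping equilibrium (symmetric crossing) is
#' `1 + k_on/k_off`; how closely and how fast a finite cell approaches it
#' depends on diffusion supply, `P_crossing`, and the contact size, which is
#' why enrichment is reported as a timecourse rather than asserted.
#'
#' @param g `smf_geometry` with exactly one trapping sub-region.
#' @param n_molecules Number of molecules.
#' @param times Times at which to record enrichment, s.
#' @param dt Engine step, s.
#' @param seed Optional seed.
#' @return `data.frame(time, enrichment)`.
#' @export
enrichment_timecourse <- function(g, n_molecules, times = seq(0, 200, by = 20),
                                  dt = 0.1, seed = NULL) {
  stopifnot(length(g$sub_regions) == 1L)
  if (!is.null(seed)) set.seed(seed)
  a_contact <- polygon_area(g$sub_regions[[1L]]$polygon)
  a_free <- polygon_area(g$cell_outline$polygon) - a_contact
  mols <- initialize_positions(n_molecules, g, mode = "uniform")
  steps <- round(sort(times) / dt)
  out <- numeric(length(steps))
  cur <- 0L
  for (i in seq_along(steps)) {
    while (cur < steps[i]) {
      mols <- step_all(mols, g, dt)
      cur <- cur + 1L
    }
    n_in <- sum(mols$region == 1L)
    out[i] <- (n_in / a_contact) / ((n_molecules - n_in) / a_free)
  }
  data.frame(time = steps * dt, enrichment = out)
}

#' Generate CNN training pairs (image + ground-truth localization map)
#'
#' Each pair is a camera frame of uniformly placed emitters rendered with the
#' Gaussian PSF plus Poisson/readout noise, together with the count map of
#' the true emitter positions on the super-resolution grid.
#'
#' @param n_images Number of pairs.
#' @param density_range `c(min, max)` expected emitters per um^2; each image
#'   draws its density uniformly in the range and its emitter count from a
#'   Poisson with mean density x field area.
#' @param psf `smf_psf`.
#' @param cam `smf_camera`.
#' @param shape Camera frame `c(n_rows, n_cols)`, pixels.
#' @param photons_per_frame Expected photons per emitter.
#' @param sr_pixel Ground-truth map pixel, um.
#' @param seed Optional seed.
#' @return List of `list(image, map, positions)`.
#' @export
generate_training_pairs <- function(n_images, density_range = c(0.1, 2),
                                    psf = psf_model(0.17),
                                    cam = camera_model(), shape = c(64, 64),
                                    photons_per_frame = 500,
                                    sr_pixel = 0.032, seed = NULL) {
  stopifnot(length(density_range) == 2L, all(density_range >= 0),
            density_range[1L] <= density_range[2L])
  if (!is.null(seed)) set.seed(seed)
  w <- shape[2L] * cam$pixel_size   # field width, um
  h <- shape[1L] * cam$pixel_size
  sr_shape <- c(ceiling(h / sr_pixel), ceiling(w / sr_pixel))
  lapply(seq_len(n_images), function(i) {
    dens <- stats::runif(1L, density_range[1L], density_range[2L])
    n <- stats::rpois(1L, dens * w * h)
    pos <- cbind(stats::runif(n, 0, w), stats::runif(n, 0, h))
    img <- render_frame(pos, psf, photons_per_frame, cam, shape)
    map <- accumulate_sr_map(data.frame(x = pos[, 1L], y = pos[, 2L]),
                             sr_pixel, sr_shape)
    list(image = img, map = map, positions = pos)
  })
}
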