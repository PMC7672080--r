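# Measurement pipelines: MSD-based diffusion estimation and histograms,
# FRAP/PAF normalization, FCS autocorrelation, contact enrichment.

#' Mean squared displacement of a trajectory
#'
#' `MSD(k)` is the average over all start points of the squared displacement
#' after `k` frames.
#'
#' @param traj `data.frame` with `x`, `y` (um) at consecutive frames.
#' @param dt Frame interval, s (attached to the result as the lag times).
#' @param max_lag Largest lag, frames; must be smaller than the trajectory
#'   length.
#' @return `data.frame(lag, tau, msd)` with `tau = lag * dt` in s and `msd`
#'   in um^2.
#' @export
compute_msd <- function(traj, dt, max_lag = 4L) {
  n <- nrow(traj)
  if (n <= max_lag)
    stop("trajectory too short (", n, " points) for max_lag = ", max_lag)
  msd <- vapply(seq_len(max_lag), function(k) {
    dx <- traj$x[(1L + k):n] - traj$x[seq_len(n - k)]
    dy <- traj$y[(1L + k):n] - traj$y[seq_len(n - k)]
    mean(dx * dx + dy * dy)
  }, numeric(1))
  data.frame(lag = seq_len(max_lag), tau = seq_len(max_lag) * dt, msd = msd)
}

#' Estimate a diffusion coefficient from one trajectory
#'
#' Ordinary least squares of `MSD(k)` for `k = 1..4` against `k * dt` with a
#' free intercept (the intercept absorbs the localization-noise offset
#' `4 * sigma_loc^2`); `D = slope / 4`.  Trajectories whose net displacement
#' is below the localization precision, or whose fitted slope is not
#' positive, cannot be meaningfully fitted and are assigned the
#' conventional floor value `1e-5` um^2/s.
#'
#' @param traj `data.frame(frame, x, y)`.
#' @param dt Frame interval, s.
#' @param loc_precision Localization precision, um (conventional 0.05 for
#'   uPAINT).
#' @param n_fit_points MSD points entering the linear fit.
#' @return Diffusion coefficient, um^2/s.
#' @export
estimate_D <- function(traj, dt, loc_precision = 0.05, n_fit_points = 4L) {
  m <- compute_msd(traj, dt, max_lag = n_fit_points)
  n <- nrow(traj)
  net <- sqrt((traj$x[n] - traj$x[1L])^2 + (traj$y[n] - traj$y[1L])^2)
  if (net < loc_precision) return(1e-5)
  slope <- stats::cov(m$tau, m$msd) / stats::var(m$tau)
  if (slope <= 0) return(1e-5)
  slope / 4
}

#' Histogram of per-trajectory diffusion coefficients
#'
#' Applies the minimum-length selection (trajectories longer than
#' `min_length` frames), estimates D per trajectory, and bins `log10(D)`;
#' floor-valued trajectories land in the lowest bin.
#'
#' @param trajs List of trajectories.
#' @param dt Frame interval, s.
#' @param loc_precision Localization precision, um.
#' @param bins Strictly increasing `log10(D)` bin edges; the conventional
#'   semi-log histogram uses 36 bins.
#' @param min_length Minimum trajectory length, frames (exclusive:
#'   trajectories must be longer than this).
#' @return List of class `smf_dhist`: `breaks`, `counts`, `fraction`,
#'   `D` (the per-trajectory estimates), `n_selected`.
#' @export
diffusion_histogram <- function(trajs, dt, loc_precision = 0.05,
                                bins = seq(-5, 1, length.out = 37),
                                min_length = 20L) {
  if (any(diff(bins) <= 0)) stop("'bins' must be strictly increasing")
  keep <- vapply(trajs, nrow, integer(1)) > min_length
  D <- vapply(trajs[keep], estimate_D, numeric(1),
              dt = dt, loc_precision = loc_precision)
  lg <- pmin(pmax(log10(D), bins[1L]), bins[length(bins)])
  counts <- if (length(lg))
    tabulate(findInterval(lg, bins, rightmost.closed = TRUE),
             nbins = length(bins) - 1L)
  else integer(length(bins) - 1L)
  structure(list(breaks = bins, counts = counts,
                 fraction = if (sum(counts)) counts / sum(counts) else counts,
                 D = D, n_selected = sum(keep)),
            class = "smf_dhist")
}

#' Normalize a FRAP curve
#'
#' Subtracts the background, then rescales affinely so that the baseline
#' mean maps to 1 and the first post-bleach value maps to 0.
#'
#' @param curve `data.frame(time, intensity)` of raw ROI intensity.
#' @param t_bleach_end End of the bleach pulse, s; the first frame at or
#'   after it is "time zero after photobleaching".
#' @param t_bleach_start Start of the pulse, s; frames strictly before it
#'   form the baseline (defaults to `t_bleach_end`).
#' @param background Background level subtracted first (for simulated data
#'   the camera offset, or 0 for count-based curves).
#' @return `data.frame(time, intensity)` normalized.
#' @export
normalize_frap <- function(curve, t_bleach_end,
                           t_bleach_start = t_bleach_end, background = 0) {
  I <- curve$intensity - background
  base_idx <- curve$time < t_bleach_start
  if (sum(base_idx) < 2L) stop("need at least 2 baseline points")
  post_idx <- which(curve$time >= t_bleach_end)
  if (length(post_idx) == 0L) stop("no post-bleach frames")
  base <- mean(I[base_idx])
  post0 <- I[post_idx[1L]]
  if (abs(base - post0) < .Machine$double.eps * max(1, abs(base)))
    stop("degenerate normalization: baseline equals first post-bleach value")
  data.frame(time = curve$time, intensity = (I - post0) / (base - post0))
}

#' Normalize a PAF curve
#'
#' `(I(t) - baseline) / (I_peak_post_pulse - baseline)`: the pre-pulse
#' baseline maps to 0 and the maximal intensity recorded after the
#' activation pulse maps to 1.
#'
#' @param curve `data.frame(time, intensity)`.
#' @param pulse_end End of the activation pulse, s.
#' @param pulse_start Start of the pulse, s (defaults to `pulse_end`);
#'   frames strictly before it form the baseline.
#' @return `data.frame(time, intensity)` normalized.
#' @export
normalize_paf <- function(curve, pulse_end, pulse_start = pulse_end) {
  base_idx <- curve$time < pulse_start
  if (sum(base_idx) < 1L) stop("need at least 1 pre-pulse baseline point")
  post <- curve$intensity[curve$time >= pulse_end]
  if (length(post) == 0L) stop("no post-pulse frames")
  base <- mean(curve$intensity[base_idx])
  peak <- max(post)
  if (abs(peak - base) < .Machine$double.eps * max(1, abs(peak)))
    stop("degenerate normalization: no activation signal above baseline")
  data.frame(time = curve$time,
             intensity = (curve$intensity - base) / (peak - base))
}

#' Normalized intensity autocorrelation (FCS)
#'
#' Subtracts the mean camera noise, computes the fluctuation autocorrelation
#' `G(k) = <dI(t) dI(t+k)> / <I>^2` (biased divide-by-N lag products), and
#' returns `G(k) / G(first_lag)` for `k >= first_lag`.  Lag 0 is excluded by
#' default as shot-noise dominated; set `first_lag = 0` to normalize by the
#' zero-lag value instead.
#'
#' @param series Numeric intensity vector or `data.frame(t, intensity)`.
#' @param camera_noise_mean Mean camera noise level to subtract.
#' @param max_lag Largest lag returned, samples.
#' @param first_lag Lag used for normalization (1 = first nonzero lag).
#' @return `data.frame(lag, G)`; attribute `"G_raw"` holds the
#'   unnormalized values.
#' @export
autocorrelate <- function(series, camera_noise_mean = 0, max_lag = NULL,
                          first_lag = 1L) {
  I <- if (is.data.frame(series)) series$intensity else series
  n <- length(I)
  if (n < 100L) stop("series too short for autocorrelation (need >= 100)")
  I <- I - camera_noise_mean
  if (stats::var(I) == 0) stop("constant series: zero variance")
  if (is.null(max_lag)) max_lag <- min(n %/% 4L, 5000L)
  ac <- stats::acf(I, lag.max = max_lag, type = "covariance",
                   plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
  G_raw <- ac / mean(I)^2                     # lags 0..max_lag
  lags <- first_lag:max_lag
  G0 <- G_raw[first_lag + 1L]
  if (G0 == 0) stop("normalization lag has zero autocorrelation")
  out <- data.frame(lag = lags, G = G_raw[lags + 1L] / G0)
  attr(out, "G_raw") <- G_raw
  out
}

#' Fit the 2D-diffusion FCS model to a normalized autocorrelation
#'
#' Least-squares fit of `G(tau) = A / (1 + tau / tau_D)`, the closed form
#' for free 2D diffusion through a Gaussian spot, for which
#' `tau_D = sigma_beam^2 / D`.
#'
#' @param acf_df `data.frame(lag, G)` from [autocorrelate()].
#' @param dt Sample interval, s.
#' @param tau_max Fit window upper bound, s (default: all lags).
#' @param baseline If `TRUE`, fit `G = A / (1 + tau/tau_D) + B`: the free
#'   offset absorbs the slowly-relaxing baseline left by finite traces in
#'   finite geometries.
#' @return Named vector `c(tau_D, A)` (and `B` when `baseline`).
#' @export
fit_fcs_tau <- function(acf_df, dt, tau_max = Inf, baseline = FALSE) {
  tau <- acf_df$lag * dt
  keep <- tau <= tau_max
  d <- data.frame(tau = tau[keep], G = acf_df$G[keep])
  # start tau_D at the half-decay point of the (lightly smoothed) curve
  Gs <- stats::filter(d$G, rep(1 / 5, 5), sides = 2)
  half <- which(Gs < (max(Gs, na.rm = TRUE) + min(Gs, na.rm = TRUE)) / 2)[1L]
  t0 <- if (is.na(half)) stats::median(d$tau) else max(d$tau[half], dt)
  fit <- if (baseline)
    stats::nls(G ~ A / (1 + tau / tauD) + B, data = d,
               start = list(A = 1, tauD = t0, B = 0),
               algorithm = "port", lower = c(A = 0, tauD = dt / 10, B = -1))
  else
    stats::nls(G ~ A / (1 + tau / tauD), data = d,
               start = list(A = 1, tauD = t0),
               algorithm = "port", lower = c(A = 0, tauD = dt / 10))
  cf <- stats::coef(fit)
  out <- c(tau_D = unname(cf[["tauD"]]), A = unname(cf[["A"]]))
  if (baseline) out <- c(out, B = unname(cf[["B"]]))
  out
}

#' Contact enrichment
#'
#' Ratio of molecular density (positions) or background-subtracted mean
#' intensity (image) in a contact region to that in a reference region.
#'
#' @param x Either an n x 2 position matrix / `data.frame(x, y)`, or a list
#'   `list(image, pixel_size)` with an intensity matrix (row = y, col = x).
#' @param contact,reference Disjoint `smf_region`s.
#' @param background Intensity background (image input only).
#' @return Enrichment ratio (contact / reference).
#' @export
enrichment <- function(x, contact, reference, background = 0) {
  stopifnot(inherits(contact, "smf_region"), inherits(reference, "smf_region"))
  mean_in <- function(r) {
    if (is.list(x) && !is.null(x$image)) {
      img <- x$image; s <- x$pixel_size
      ctr <- expand.grid(cx = (seq_len(ncol(img)) - 0.5) * s,
                         cy = (seq_len(nrow(img)) - 0.5) * s)
      inside <- point_in_polygon(ctr$cx, ctr$cy, r$polygon)
      if (!any(inside)) stop("region '", r$name, "' covers no pixels")
      mean(t(img)[inside]) - background
    } else {
      p <- if (is.data.frame(x)) cbind(x$x, x$y) else rbind(x)
      sum(point_in_polygon(p[, 1L], p[, 2L], r$polygon)) /
        polygon_area(r$polygon)
    }
  }
  ref <- mean_in(reference)
  if (ref <= 0) stop("empty reference region: enrichment undefined")
  cnt <- mean_in(contact)
  cnt / ref
}
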