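# Brownian motion with region-dependent diffusion and two-state trapping
# kinetics.  All per-step operations are vectorized over molecules.

#' Molecule population state
#'
#' The engine's container for a population of independent molecules: one row
#' per molecule with continuous position (um), kinetic state and fluorophore
#' state.
#'
#' @param x,y Positions in um.
#' @param bound Logical: trapped (bound) vs free.
#' @param region Integer index of the containing sub-region (0 = outside all
#'   sub-regions, i.e. in the cell outline pool).
#' @param fluor Integer fluorophore state code; see [fluor_codes].
#' @return `data.frame` with class `smf_molecules`.
#' @export
molecule_state <- function(x, y, bound = FALSE, region = 0L,
                           fluor = fluor_codes["ON"]) {
  n <- length(x)
  stopifnot(length(y) == n)
  out <- data.frame(x = x, y = y,
                    bound = rep_len(bound, n),
                    region = rep_len(as.integer(region), n),
                    fluor = rep_len(as.integer(fluor), n))
  class(out) <- c("smf_molecules", "data.frame")
  out
}

#' Sample Brownian displacements
#'
#' Each axis displacement is an independent zero-mean Gaussian with variance
#' `2 * D * dt`, so the expected squared step length is `4 * D * dt`.
#'
#' @param D Diffusion coefficient(s), um^2/s; recycled against `n`.
#' @param dt Time step, s.
#' @param n Number of displacements to draw (default `length(D)`).
#' @return `n x 2` matrix of `(dx, dy)` in um.
#' @export
sample_displacement <- function(D, dt, n = length(D)) {
  if (any(D < 0)) stop("diffusion coefficient must be >= 0")
  stopifnot(dt > 0)
  sd <- sqrt(2 * rep_len(D, n) * dt)
  cbind(stats::rnorm(n, 0, sd), stats::rnorm(n, 0, sd))
}

#' Effective diffusion coefficient of each molecule
#'
#' Trapped molecules move with their region's `D_trap`; free molecules inside
#' a sub-region use that region's `D_free` (`D_in`); free molecules outside
#' all sub-regions use the cell outline's `D_free` (`D_out`).
#'
#' @param state `smf_molecules`.
#' @param g `smf_geometry`.
#' @return Numeric vector of coefficients, um^2/s.
#' @export
effective_D <- function(state, g) {
  D <- rep(g$cell_outline$D_free, nrow(state))
  for (k in seq_along(g$sub_regions)) {
    in_k <- state$region == k
    D[in_k] <- g$sub_regions[[k]]$D_free
    D[in_k & state$bound] <- g$sub_regions[[k]]$D_trap
  }
  D
}

#' Update the free/trapped kinetic state over one time step
#'
#' First-order kinetics with at most one transition per step and exact
#' exponential transition probabilities `1 - exp(-k * dt)` (not the linear
#' approximation, which fails for large `k * dt`).
#'
#' @param bound Logical vector: current trapped state.
#' @param in_trap_region Logical vector: molecule currently inside a region
#'   with `k_on > 0`.
#' @param k_on,k_off Binding/unbinding rates, 1/s (vectors recycled).
#' @param dt Time step, s.
#' @return Updated logical `bound` vector.
#' @export
update_binding <- function(bound, in_trap_region, k_on, k_off, dt) {
  if (any(k_on < 0) || any(k_off < 0)) stop("kinetic rates must be >= 0")
  n <- length(bound)
  u <- stats::runif(n)
  p_bind <- 1 - exp(-rep_len(k_on, n) * dt)
  p_unbind <- 1 - exp(-rep_len(k_off, n) * dt)
  binds <- !bound & in_trap_region & u < p_bind
  unbinds <- bound & u < p_unbind
  (bound | binds) & !unbinds
}

#' Advance all molecules by one time step
#'
#' Fixed, documented operation order per molecule: (1) binding/unbinding is
#' evaluated from the pre-move region; (2) a Brownian displacement is drawn
#' with the molecule's effective diffusion coefficient; (3) the move is
#' resolved against the geometry (outline reflection, probabilistic border
#' crossing).  Bound molecules are tethered: their crossing attempts out of
#' the trapping region are always rejected.  Molecules are statistically
#' independent.
#'
#' @param molecules `smf_molecules`.
#' @param g `smf_geometry`.
#' @param dt Time step, s.
#' @return Updated `smf_molecules`.
#' @export
step_all <- function(molecules, g, dt) {
  n <- nrow(molecules)
  if (n == 0L) return(molecules)

  # fast path: a single uniform rectangular region needs no kinetics, no
  # polygon tests and no crossing logic -- folding reflection is exact
  if (length(g$sub_regions) == 0L && !is.null(g$fast_rect)) {
    if (g$cell_outline$D_free == 0) return(molecules)
    disp <- sample_displacement(g$cell_outline$D_free, dt, n)
    molecules$x <- fold_reflect(molecules$x + disp[, 1L],
                                g$fast_rect$x[1L], g$fast_rect$x[2L])
    molecules$y <- fold_reflect(molecules$y + disp[, 2L],
                                g$fast_rect$y[1L], g$fast_rect$y[2L])
    return(molecules)
  }
  reg <- molecules$region

  kon <- koff <- numeric(n)
  for (k in seq_along(g$sub_regions)) {
    in_k <- reg == k
    kon[in_k] <- g$sub_regions[[k]]$k_on
    koff[in_k] <- g$sub_regions[[k]]$k_off
  }
  molecules$bound <- update_binding(molecules$bound, kon > 0, kon, koff, dt)

  D <- effective_D(molecules, g)
  disp <- sample_displacement(D, dt)
  res <- resolve_steps(molecules$x, molecules$y,
                       molecules$x + disp[, 1L], molecules$y + disp[, 2L],
                       g, reg0 = reg, confined = molecules$bound)
  molecules$x <- res$x
  molecules$y <- res$y
  molecules$region <- res$region
  molecules
}

#' Place molecules in the geometry
#'
#' `mode = "uniform"` rejection-samples positions uniformly over the cell
#' outline with all molecules free; `mode = "equilibrated"` additionally runs
#' `warmup_steps` of [step_all()] before time zero so that trapping occupancy
#' and contact enrichment approach their steady state.
#'
#' @param n Number of molecules.
#' @param g `smf_geometry`.
#' @param mode `"uniform"` or `"equilibrated"`.
#' @param warmup_steps Steps of pre-equilibration (equilibrated mode).
#' @param dt Time step used during warm-up, s.
#' @return `smf_molecules`.
#' @export
initialize_positions <- function(n, g, mode = c("uniform", "equilibrated"),
                                 warmup_steps = 0L, dt = 0.02) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  poly <- g$cell_outline$polygon
  if (polygon_area(poly) <= 0) stop("cell outline has zero area")
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  xs <- ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 100L)
    cx <- stats::runif(m, xr[1L], xr[2L])
    cy <- stats::runif(m, yr[1L], yr[2L])
    keep <- point_in_polygon(cx, cy, poly)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]
  mols <- molecule_state(xs, ys, bound = FALSE,
                         region = region_index(xs, ys, g))
  if (mode == "equilibrated" && warmup_steps > 0L)
    for (i in seq_len(warmup_steps)) mols <- step_all(mols, g, dt)
  mols
}

#' Simulate unconstrained free-diffusion trajectories
#'
#' Pure Brownian walks with a single diffusion coefficient and no geometry,
#' used by the diffusion-estimation pipeline tests and calibration runs.
#'
#' @param n Number of trajectories.
#' @param n_steps Steps per trajectory (trajectory has `n_steps + 1` points).
#' @param D Diffusion coefficient, um^2/s.
#' @param dt Frame interval, s.
#' @return List of trajectories, each a `data.frame(frame, x, y)` with
#'   1-based consecutive frames.
#' @export
simulate_free_trajectories <- function(n, n_steps, D, dt) {
  stopifnot(n >= 1, n_steps >= 1)
  sd <- sqrt(2 * D * dt)
  lapply(seq_len(n), function(i) {
    dx <- stats::rnorm(n_steps, 0, sd)
    dy <- stats::rnorm(n_steps, 0, sd)
    data.frame(frame = seq_len(n_steps + 1L),
               x = c(0, cumsum(dx)), y = c(0, cumsum(dy)))
  })
}
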