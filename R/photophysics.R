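# Fluorophore photophysics: a four-state chain
#   PREACTIVE --k_activ--> OFF <--k_on_fluo/k_off_fluo--> ON --k_bleach--> BLEACHED
# with activation and bleaching gated by laser pulses in space and time.
# BLEACHED is absorbing.

#' Fluorophore state codes
#'
#' Integer codes used in the `fluor` column of [molecule_state()]:
#' `PREACTIVE` (photoactivatable, not yet switchable), `OFF` (dark but
#' switchable), `ON` (emitting), `BLEACHED` (absorbing).
#' @export
fluor_codes <- c(PREACTIVE = 0L, OFF = 1L, ON = 2L, BLEACHED = 3L)

#' Fluorophore photophysical parameters
#'
#' @param k_on_fluo OFF -> ON switch-on rate, 1/s.
#' @param k_off_fluo ON -> OFF switch-off rate, 1/s.
#' @param k_bleach ON -> BLEACHED rate, 1/s; applied only where and when a
#'   bleach pulse is active.
#' @param k_activ PREACTIVE -> OFF photoactivation rate, 1/s; applied only
#'   where and when an activation pulse is active.
#' @param photons_per_frame Expected photons emitted per frame while ON.
#' @return List of class `smf_fluor_params`.
#' @export
fluor_params <- function(k_on_fluo = 1, k_off_fluo = 3, k_bleach = 0,
                         k_activ = 0, photons_per_frame = 500) {
  stopifnot(k_on_fluo >= 0, k_off_fluo >= 0, k_bleach >= 0, k_activ >= 0,
            photons_per_frame >= 0)
  structure(list(k_on_fluo = k_on_fluo, k_off_fluo = k_off_fluo,
                 k_bleach = k_bleach, k_activ = k_activ,
                 photons_per_frame = photons_per_frame),
            class = "smf_fluor_params")
}

#' Advance fluorophore states by one time step
#'
#' Transitions fire with probability `1 - exp(-k * dt)`.  Competing exits
#' from ON (switch-off vs bleaching) are resolved by sampling one exponential
#' waiting time per channel and taking the minimum, which reproduces the
#' correct branching ratios for any `dt`.  Only ON molecules bleach:
#' ground-state dark molecules absorb weakly, and this makes `k_bleach`
#' directly the fitted fluorescence-loss rate.
#'
#' @param fluor Integer state vector (see [fluor_codes]).
#' @param p `smf_fluor_params`.
#' @param dt Time step, s.
#' @param bleach_active Logical vector: bleach pulse covers the molecule now.
#' @param activ_active Logical vector: activation pulse covers the molecule.
#' @return Updated integer state vector.
#' @export
update_fluor <- function(fluor, p, dt, bleach_active = FALSE,
                         activ_active = FALSE) {
  stopifnot(dt > 0)
  n <- length(fluor)
  bleach_active <- rep_len(bleach_active, n)
  activ_active <- rep_len(activ_active, n)
  out <- fluor

  pre <- fluor == fluor_codes[["PREACTIVE"]] & activ_active
  if (any(pre) && p$k_activ > 0)
    out[pre][stats::runif(sum(pre)) < 1 - exp(-p$k_activ * dt)] <-
      fluor_codes[["OFF"]]

  off <- fluor == fluor_codes[["OFF"]]
  if (any(off) && p$k_on_fluo > 0)
    out[off][stats::runif(sum(off)) < 1 - exp(-p$k_on_fluo * dt)] <-
      fluor_codes[["ON"]]

  on <- which(fluor == fluor_codes[["ON"]])
  if (length(on)) {
    t_off <- if (p$k_off_fluo > 0) stats::rexp(length(on), p$k_off_fluo) else Inf
    k_bl <- ifelse(bleach_active[on], p$k_bleach, 0)
    t_bl <- rep(Inf, length(on))
    pos <- k_bl > 0
    if (any(pos)) t_bl[pos] <- stats::rexp(sum(pos), k_bl[pos])
    t_exit <- pmin(t_off, t_bl)
    fires <- t_exit < dt
    out[on[fires & t_bl < t_off]] <- fluor_codes[["BLEACHED"]]
    out[on[fires & t_off <= t_bl]] <- fluor_codes[["OFF"]]
  }
  out
}

# Exponential dwell draw that tolerates rate 0 (never fires).
rexp0 <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
}

# Event-based alternating OFF/ON renewal process for n molecules over [0, T].
# Returns a data.frame(mol, t_on, t_off) of ON intervals clipped to [0, T].
# `initial` = "off" (all dark at t = 0, e.g. dyes pumped to a dark state
# before a STORM sequence) or "equilibrium" (ON with probability
# k_on/(k_on+k_off); memorylessness makes the residual dwell exponential).
blink_bursts <- function(n, k_on, k_off, duration, initial = c("off", "equilibrium")) {
  initial <- match.arg(initial)
  t_cur <- numeric(n)
  bursts <- list()
  if (initial == "equilibrium" && (k_on + k_off) > 0) {
    start_on <- stats::runif(n) < k_on / (k_on + k_off)
    if (any(start_on)) {
      b <- pmin(rexp0(sum(start_on), k_off), duration)
      bursts[[1L]] <- data.frame(mol = which(start_on), t_on = 0, t_off = b)
      t_cur[start_on] <- b
    }
  }
  repeat {
    act <- which(t_cur < duration)
    if (length(act) == 0L) break
    if (k_on <= 0) break                       # dark forever
    a <- t_cur[act] + rexp0(length(act), k_on) # burst start
    b <- a + rexp0(length(act), k_off)         # burst end
    keep <- a < duration
    if (any(keep))
      bursts[[length(bursts) + 1L]] <-
        data.frame(mol = act[keep], t_on = a[keep],
                   t_off = pmin(b[keep], duration))
    t_cur[act] <- b
  }
  if (length(bursts) == 0L)
    return(data.frame(mol = integer(0), t_on = numeric(0), t_off = numeric(0)))
  out <- do.call(rbind, bursts)
  out[out$t_off > out$t_on, , drop = FALSE]
}

# Frame-detection counting from ON intervals.  rule = "overlap": a frame
# counts when the burst covers at least half of it; with the burst phase
# uniform this is an unbiased estimate of on-time/dt (fractional-overlap
# counting with integer detections).  rule = "midpoint": a frame counts when
# the burst covers the frame midpoint (matches the per-step engine).
# Returns per-burst first/last detected frame (0-based) and count.
burst_frames <- function(t_on, t_off, dt, n_frames, rule = c("overlap", "midpoint")) {
  rule <- match.arg(rule)
  t_end <- n_frames * dt
  a <- pmax(t_on, 0); b <- pmin(t_off, t_end)
  if (rule == "midpoint") {
    f0 <- ceiling(a / dt - 0.5)
    f1 <- ceiling(b / dt - 0.5) - 1
  } else {
    fa <- floor(a / dt)
    fb <- ceiling(b / dt) - 1          # frame containing the last instant
    cov_first <- pmin(b, (fa + 1) * dt) - a
    cov_last <- b - pmax(a, fb * dt)
    single <- fb <= fa
    f0 <- ifelse(single, fa, fa + (cov_first < dt / 2))
    f1 <- ifelse(single,
                 fa - (cov_first < dt / 2),  # cov_first = b - a here
                 fb - (cov_last < dt / 2))
  }
  f0 <- as.integer(pmax(f0, 0)); f1 <- as.integer(pmin(f1, n_frames - 1))
  cnt <- pmax(f1 - f0 + 1L, 0L)
  list(first = f0, last = f1, count = cnt)
}

#' Simulate a blinking trace of a single immobile fluorophore
#'
#' Event-based sampling of exponential ON/OFF dwell times, binned to the
#' frame interval by the frame-midpoint rule; dwell times themselves carry no
#' discretization error.
#'
#' @param p `smf_fluor_params` (only `k_on_fluo`, `k_off_fluo` are used).
#' @param duration Total trace duration, s.
#' @param dt Frame interval, s.
#' @param initial `"off"` or `"equilibrium"` initial state.
#' @return `data.frame(t, on)`: frame start times and 0/1 emission; the ON
#'   intervals are attached as attribute `"bursts"`.
#' @export
simulate_blink_trace <- function(p, duration, dt, initial = c("off", "equilibrium")) {
  stopifnot(duration >= dt)
  initial <- match.arg(initial)
  n_frames <- floor(duration / dt)
  bursts <- blink_bursts(1L, p$k_on_fluo, p$k_off_fluo, n_frames * dt, initial)
  on <- integer(n_frames)
  if (nrow(bursts)) {
    bf <- burst_frames(bursts$t_on, bursts$t_off, dt, n_frames, "midpoint")
    keep <- bf$count > 0
    if (any(keep)) {
      idx <- sequence(bf$count[keep], from = bf$first[keep] + 1L, by = 1L)
      on[idx] <- 1L
    }
  }
  out <- data.frame(t = (seq_len(n_frames) - 1L) * dt, on = on)
  attr(out, "bursts") <- bursts
  out
}

#' Estimate blinking rates from a binary emission trace
#'
#' Rates are the reciprocals of the mean ON and OFF dwell times; the dwells
#' touching either end of the trace are censored and excluded.
#'
#' @param trace `data.frame(t, on)` or a 0/1 vector of frame states.
#' @param dt Frame interval, s.
#' @return Named vector `c(k_on_fluo, k_off_fluo)` in 1/s.
#' @export
fit_blinking_rates <- function(trace, dt) {
  on <- if (is.data.frame(trace)) trace$on else trace
  r <- rle(as.integer(on))
  if (length(r$lengths) < 3L)
    stop("trace has no uncensored dwell; cannot estimate rates")
  keep <- seq(2L, length(r$lengths) - 1L)   # interior (uncensored) dwells
  on_dwell <- r$lengths[keep][r$values[keep] == 1L] * dt
  off_dwell <- r$lengths[keep][r$values[keep] == 0L] * dt
  if (length(on_dwell) == 0L || length(off_dwell) == 0L)
    stop("trace needs at least one uncensored ON and one uncensored OFF dwell")
  c(k_on_fluo = 1 / mean(off_dwell), k_off_fluo = 1 / mean(on_dwell))
}
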