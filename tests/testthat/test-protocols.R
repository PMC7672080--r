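test_that("make_fixture_geometry: analytic areas and containment guard", {
  g <- make_fixture_geometry(cell = c(20, 20),
                             contact = list(center = c(10, 10), radius = 5),
                             n_vertices = 256L)
  expect_equal(polygon_area(g$cell_outline$polygon), 400)
  # regular n-gon area -> pi r^2 as n grows; at 256 vertices within 0.05%
  expect_within(polygon_area(g$sub_regions[[1]]$polygon), pi * 25, 5e-4)
  expect_error(make_fixture_geometry(cell = c(10, 10),
                                     contact = list(center = c(9, 5),
                                                    radius = 3)),
               "not contained")
  # strip contact spans the cell height
  gs <- make_fixture_geometry(cell = c(20, 10),
                              contact = list(strip = c(8, 12)))
  expect_equal(polygon_area(gs$sub_regions[[1]]$polygon), 40)
})

test_that("run_spt: trajectory bookkeeping and dwell statistics", {
  g <- fixture_free()
  # k_off_fluo = 0, all start ON -> every trajectory spans all frames
  res <- run_spt(g, 40, fluor_params(k_on_fluo = 1, k_off_fluo = 0),
                 n_frames = 50, seed = 36)
  expect_length(res$trajectories, 40)
  expect_true(all(vapply(res$trajectories, nrow, integer(1)) == 50))

  # mean trajectory length ~ 1/(k_off_fluo * dt) = 16.7 frames
  res <- run_spt(g, 200, fluor_params(k_on_fluo = 1, k_off_fluo = 3),
                 n_frames = 2000, dt = 0.02, seed = 37)
  lens <- vapply(res$trajectories, nrow, integer(1))
  expect_within(mean(lens), 1 / (3 * 0.02), 0.05)
  # frames within a trajectory are consecutive
  expect_true(all(vapply(res$trajectories,
                         function(d) all(diff(d$frame) == 1), logical(1))))
})

test_that("run_spt renders a camera stack on request", {
  g <- fixture_free(cell = c(6, 6))
  r <- run_spt(g, 10, n_frames = 5, seed = 51, render = TRUE,
               cam = camera_model(offset = 100, readout_sigma = 2,
                                  pixel_size = 0.16))
  expect_length(r$stack, 5)
  expect_equal(dim(r$stack[[1]]), c(ceiling(6 / 0.16), ceiling(6 / 0.16)))
  expect_gt(mean(r$stack[[1]]), 99)   # offset floor plus signal
})

test_that("run_spt: localization noise does not perturb the motion stream", {
  g <- fixture_free()
  r1 <- run_spt(g, 50, n_frames = 300, loc_sigma = 0, seed = 38)
  r2 <- run_spt(g, 50, n_frames = 300, loc_sigma = 0.05, seed = 38)
  expect_identical(r1$detections[c("mol", "frame")],
                   r2$detections[c("mol", "frame")])
  err <- r2$detections$x - r1$detections$x
  expect_within(sd(err), 0.05, 0.05)
})

test_that("run_storm: detection budget, linearity, SR conservation", {
  g0 <- make_fixture_geometry(cell = c(10, 10), contact = NULL, D_out = 0)
  none <- run_storm(g0, 500, fluor_params(k_on_fluo = 0, k_off_fluo = 9.3),
                    n_frames = 500, seed = 39, mode = "count")
  expect_equal(none$n_detections, 0)

  r <- run_storm(g0, 4000, n_frames = 16000, seed = 40)
  expect_within(r$n_detections, r$expected_detections, 0.025)
  # map conserves every detection inside its bounds (jitter can push a
  # borderline localization out of the 10 x 10 um field)
  ext <- dim(r$sr_map) * 0.032             # c(ny, nx) * sr_pixel
  in_map <- r$detections$x >= 0 & r$detections$x < ext[2] &
    r$detections$y >= 0 & r$detections$y < ext[1]
  expect_identical(sum(r$sr_map), sum(in_map))
  expect_identical(nrow(r$detections), r$n_detections)

  # halving k_on_fluo halves the expectation and the realized count follows
  rh <- run_storm(g0, 4000, fluor_params(k_on_fluo = 0.003, k_off_fluo = 9.3),
                  n_frames = 16000, seed = 40, mode = "count")
  expect_within(rh$expected_detections, r$expected_detections / 2, 0.002)
  expect_within(rh$n_detections, r$n_detections / 2, 0.05)

  expect_warning(run_storm(fixture_free(), 100, n_frames = 100, seed = 1,
                           mode = "count"), "immobile")
})

test_that("run_frap: no-bleach flatness and the no-exchange closed form", {
  g0 <- make_fixture_geometry(cell = c(20, 20), contact = NULL, D_out = 0)
  prot0 <- frap_protocol(rbind(c(10, 10)), bleach_rate = 0, dt = 0.05,
                         recovery_offsets = c(0, 1, 2, 5))
  r0 <- run_frap(g0, 5000, protocol = prot0, seed = 41)
  expect_equal(length(unique(r0$curves[, 1])), 1L)  # flat: immobile, no bleach

  # immobile molecules, k_bleach = 4.25 for 0.4 s: survival = exp(-1.7)
  prot <- frap_protocol(rbind(c(10, 10)), dt = 0.05,
                        recovery_offsets = c(0, 2, 10, 40))
  r <- run_frap(g0, 100000, protocol = prot, seed = 42)
  base <- mean(r$curves[r$time < 10, 1])
  post <- r$curves[r$time >= prot$t_pulse_end, 1]
  expect_within(post[1] / base, exp(-1.7), 0.08)    # 0.1827
  expect_equal(length(unique(post)), 1L)            # no recovery afterwards
})

test_that("run_paf: activation gating and closed-form activated fraction", {
  g0 <- make_fixture_geometry(cell = c(20, 20), contact = NULL, D_out = 0)
  prot0 <- paf_protocol(rbind(c(10, 10)), activation_rate = 0, dt = 0.05,
                        decay_offsets = c(0, 1, 5))
  r0 <- run_paf(g0, 3000, protocol = prot0, seed = 43)
  expect_true(all(r0$curves == 0))                  # no signal at all

  # activation 1/s for 0.3 s -> 1 - exp(-0.3) = 0.2592 of PREACTIVE in ROI
  prot <- paf_protocol(rbind(c(10, 10)), activation_duration = 0.3,
                       activation_rate = 1, dt = 0.05,
                       decay_offsets = c(0, 1, 2, 5, 20))
  r <- run_paf(g0, 100000, fluor_params(k_on_fluo = 100, k_off_fluo = 0),
               protocol = prot, seed = 44)
  # realized ROI population from the final (immobile) molecule state
  m <- r$molecules
  in_roi <- smfsim:::in_circle(m$x, m$y, c(10, 10), 1.4)
  post <- r$curves[r$time >= prot$t_pulse_end + 1, 1]
  expect_within(mean(post) / sum(in_roi), 1 - exp(-0.3), 0.06)
  # immobile activated molecules, no bleaching: flat post-pulse curve
  expect_equal(length(unique(post)), 1L)
})

test_that("PAF decay mirrors FRAP recovery of the mobile fraction", {
  # near-total pulses (rate 20/s for 0.4 s) with identical transport: the
  # normalized curves are complementary; 4 ROIs averaged, 40k molecules,
  # bounds set by the per-frame counting noise (~5%)
  g <- fixture_free(cell = c(40, 40))
  offs <- c(0, 1, 2, 4, 8, 15, 25, 40)
  centers <- rbind(c(12, 12), c(28, 12), c(12, 28), c(28, 28))
  fr <- run_frap(g, 40000,
                 protocol = frap_protocol(centers, bleach_rate = 20,
                                          dt = 0.05, recovery_offsets = offs),
                 seed = 45)
  pa <- run_paf(g, 40000, fluor_params(k_on_fluo = 1000, k_off_fluo = 0),
                protocol = paf_protocol(centers, activation_rate = 20,
                                        activation_duration = 0.4, dt = 0.05,
                                        decay_offsets = offs),
                seed = 45)
  f_rec <- p_dec <- 0
  for (r in 1:4) {
    fn <- normalize_frap(data.frame(time = fr$time, intensity = fr$curves[, r]),
                         t_bleach_end = fr$protocol$t_pulse_end,
                         t_bleach_start = fr$protocol$t_pulse_start)
    pn <- normalize_paf(data.frame(time = pa$time, intensity = pa$curves[, r]),
                        pulse_end = pa$protocol$t_pulse_end,
                        pulse_start = pa$protocol$t_pulse_start)
    f_rec <- f_rec + fn$intensity[fn$time >= fr$protocol$t_pulse_end] / 4
    p_dec <- p_dec + pn$intensity[pn$time >= pa$protocol$t_pulse_end] / 4
  }
  expect_length(f_rec, length(p_dec))
  expect_lt(mean(abs(f_rec + p_dec - 1)), 0.06)
  expect_lt(max(abs(f_rec + p_dec - 1)), 0.15)
})

test_that("run_fcs: pinned molecule, beam validation, sample rates", {
  g0 <- make_fixture_geometry(cell = c(4, 4), contact = NULL, D_out = 0)
  one <- molecule_state(x = 2, y = 2)
  tr <- run_fcs(g0, 1, beam = fcs_beam(c(2, 2), 0.25, 1, 500),
                n_samples = 200, seed = 46, molecules = one)
  expect_true(all(tr$intensity == 500))   # weight 1 x photons_per_frame

  off_center <- molecule_state(x = 2.25, y = 2)
  tr2 <- run_fcs(g0, 1, beam = fcs_beam(c(2, 2), 0.25, 1, 200),
                 n_samples = 100, seed = 46, molecules = off_center)
  expect_equal(unique(tr2$intensity), 500 * exp(-0.5))
  expect_equal(diff(tr2$t[1:2]), 1 / 200)

  expect_error(run_fcs(g0, 10, beam = fcs_beam(c(9, 9), 0.25, 1, 500),
                       n_samples = 100, seed = 1),
               "not inside the cell outline")
})

test_that("generate_training_pairs: conservation and Poisson counts", {
  pairs <- generate_training_pairs(30, density_range = c(0.5, 0.5),
                                   shape = c(32, 32), seed = 47)
  counts <- vapply(pairs, function(p) nrow(p$positions), integer(1))
  expect_equal(vapply(pairs, function(p) sum(p$map), numeric(1)),
               as.numeric(counts))
  area <- (32 * 0.16)^2
  expect_gt(poisson.test(sum(counts), 30 * 0.5 * area)$p.value, 0.01)

  empty <- generate_training_pairs(1, density_range = c(0, 0),
                                   shape = c(16, 16), seed = 48)[[1]]
  expect_equal(sum(empty$map), 0)
  expect_equal(nrow(empty$positions), 0)
  expect_equal(dim(empty$image), c(16, 16))
})
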