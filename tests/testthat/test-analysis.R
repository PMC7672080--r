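test_that("compute_msd: stationary, ballistic and brute-force oracle", {
  still <- data.frame(frame = 1:30, x = rep(1, 30), y = rep(2, 30))
  expect_true(all(compute_msd(still, 0.02)$msd == 0))

  # uniform motion along a line: MSD(k) = (k*s)^2
  s <- 0.05
  lin <- data.frame(frame = 1:30, x = (0:29) * s, y = 0)
  expect_equal(compute_msd(lin, 0.02, 5)$msd, ((1:5) * s)^2)

  expect_error(compute_msd(still[1:4, ], 0.02, 4), "too short")

  # brute-force double-loop oracle on a random walk
  set.seed(27)
  tr <- simulate_free_trajectories(1, 40, 0.2, 0.02)[[1]]
  brute <- sapply(1:4, function(k) {
    acc <- 0
    for (i in 1:(nrow(tr) - k))
      acc <- acc + (tr$x[i + k] - tr$x[i])^2 + (tr$y[i + k] - tr$y[i])^2
    acc / (nrow(tr) - k)
  })
  expect_equal(compute_msd(tr, 0.02)$msd, brute)
})

test_that("estimate_D: floor rules and independent least-squares oracle", {
  still <- data.frame(frame = 1:30, x = rep(1, 30), y = rep(1, 30))
  expect_equal(estimate_D(still, 0.02), 1e-5)

  # net displacement below the localization precision -> floor
  set.seed(28)
  tiny <- data.frame(frame = 1:30, x = 1 + rnorm(30, 0, 1e-4),
                     y = 1 + rnorm(30, 0, 1e-4))
  tiny$x[30] <- tiny$x[1] + 0.01    # net 10 nm < 50 nm
  expect_equal(estimate_D(tiny, 0.02, loc_precision = 0.05), 1e-5)

  # lm() as the independent fitting oracle
  tr <- simulate_free_trajectories(1, 60, 0.3, 0.02)[[1]]
  m <- compute_msd(tr, 0.02, 4)
  oracle <- unname(coef(lm(msd ~ tau, m))[2] / 4)
  expect_within(estimate_D(tr, 0.02), oracle, 1e-10)
})

test_that("estimate_D recovers D for free Brownian motion (10% median)", {
  set.seed(29)
  for (D in c(0.04, 0.3)) {
    tr <- simulate_free_trajectories(400, 100, D, 0.02)
    est <- vapply(tr, estimate_D, numeric(1), dt = 0.02)
    expect_within(median(est), D, 0.10)
  }
})

test_that("diffusion_histogram: selection, conservation, bimodal recovery", {
  set.seed(30)
  short <- simulate_free_trajectories(20, 15, 0.3, 0.02)  # 16 < 21 points
  h0 <- diffusion_histogram(short, 0.02)
  expect_equal(sum(h0$counts), 0)

  mix <- c(simulate_free_trajectories(300, 60, 0.3, 0.02),
           simulate_free_trajectories(300, 60, 0.04, 0.02),
           simulate_free_trajectories(50, 10, 0.3, 0.02))  # filtered out
  h <- diffusion_histogram(mix, 0.02)
  expect_equal(sum(h$counts), 600)
  expect_equal(h$n_selected, 600)
  expect_equal(sum(h$fraction), 1)
  # the two modes sit within 2 bins of the generative values
  mids <- (h$breaks[-1] + h$breaks[-37]) / 2
  ord <- order(h$counts, decreasing = TRUE)
  top <- mids[ord[1:6]]
  expect_true(min(abs(top - log10(0.3))) < 2 * diff(h$breaks)[1])
  expect_true(min(abs(top - log10(0.04))) < 2 * diff(h$breaks)[1])
})

test_that("normalize_frap: affine identity and degenerate input", {
  curve <- data.frame(time = c(0, 1, 2, 3), intensity = c(100, 100, 20, 60))
  n <- normalize_frap(curve, t_bleach_end = 1.5)
  expect_equal(n$intensity, c(1, 1, 0, 0.5))
  flat <- data.frame(time = 0:3, intensity = rep(5, 4))
  expect_error(normalize_frap(flat, 1.5), "degenerate")
  # background subtraction is affine-invariant after normalization
  curve2 <- curve; curve2$intensity <- curve2$intensity + 30
  expect_equal(normalize_frap(curve2, 1.5, background = 30)$intensity,
               n$intensity)
})

test_that("normalize_paf: peak scaling and degenerate input", {
  curve <- data.frame(time = c(0, 1, 2), intensity = c(10, 110, 60))
  n <- normalize_paf(curve, pulse_end = 0.5)
  expect_equal(n$intensity, c(0, 1, 0.5))
  expect_error(normalize_paf(data.frame(time = 0:2, intensity = rep(3, 3)),
                             0.5), "degenerate")
})

test_that("autocorrelate: white noise, sinusoid oracle, invariances", {
  set.seed(32)
  w <- rnorm(20000)
  ac <- autocorrelate(w, max_lag = 50, first_lag = 0)  # normalize by lag 0
  expect_true(all(abs(ac$G[-1]) < 0.05))   # ~0 for all k >= 1

  t <- seq_len(5000)
  om <- 0.05
  s <- 10 + cos(om * t)
  ac <- autocorrelate(s, max_lag = 200)
  expect_within(ac$G[100] / ac$G[50], cos(om * 100) / cos(om * 50), 0.02)

  expect_error(autocorrelate(rep(1, 500)), "zero variance")
  expect_error(autocorrelate(rnorm(50)), "too short")

  # global intensity scale invariance
  set.seed(33)
  x <- 50 + cumsum(rnorm(5000)) * 0.01 + rnorm(5000)
  a1 <- autocorrelate(x, max_lag = 30)
  a2 <- autocorrelate(7 * x, max_lag = 30)
  expect_equal(a1$G, a2$G)
})

test_that("enrichment: uniform density, guards, trapping equilibrium", {
  g <- fixture_two_region()
  contact <- g$sub_regions[[1]]
  ref <- region("ref", rbind(c(0.5, 0.5), c(4, 0.5), c(4, 4), c(0.5, 4)),
                "generic_roi")
  set.seed(34)
  m <- initialize_positions(40000, fixture_free())
  e <- enrichment(data.frame(x = m$x, y = m$y), contact, ref)
  expect_within(e, 1, 0.05)
  # all molecules inside the contact: the reference is empty -> guard
  expect_error(enrichment(data.frame(x = 10, y = 10), contact, ref),
               "empty reference")

  # image input: uniform image -> 1
  img <- matrix(50, 125, 125)
  e_img <- enrichment(list(image = img, pixel_size = 0.16), contact, ref)
  expect_equal(e_img, 1)

  # equilibrated trapping: enrichment -> 1 + k_on/k_off = 11 (P_crossing 1)
  set.seed(42)
  g2 <- make_fixture_geometry(cell = c(14, 14),
                              contact = list(center = c(7, 7), radius = 3.5),
                              k_on = 0.6, k_off = 0.06, P_crossing = 1)
  m2 <- initialize_positions(2000, g2, mode = "equilibrated",
                             warmup_steps = 1500, dt = 0.1)
  ref2 <- region("ref", rbind(c(0.5, 0.5), c(3, 0.5), c(3, 3), c(0.5, 3)),
                 "generic_roi")
  e2 <- enrichment(data.frame(x = m2$x, y = m2$y), g2$sub_regions[[1]], ref2)
  expect_within(e2, 11, 0.15)
})

test_that("enrichment timecourse rises monotonically toward equilibrium", {
  g <- make_fixture_geometry(cell = c(12, 12),
                             contact = list(center = c(6, 6), radius = 3),
                             k_on = 0.6, k_off = 0.06, P_crossing = 1)
  tc <- enrichment_timecourse(g, 1500, times = c(0, 20, 60, 120), dt = 0.1,
                              seed = 35)
  expect_lt(tc$enrichment[1], 2)
  expect_true(all(diff(tc$enrichment) > 0))
  expect_gt(tc$enrichment[4], 5)
})
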