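test_that("BLEACHED is absorbing and only ON molecules bleach", {
  p <- fluor_params(k_on_fluo = 50, k_off_fluo = 50, k_bleach = 50,
                    k_activ = 50)
  set.seed(14)
  bl <- rep(fluor_codes[["BLEACHED"]], 1000)
  for (i in 1:20)
    bl <- update_fluor(bl, p, 0.1, bleach_active = TRUE, activ_active = TRUE)
  expect_true(all(bl == fluor_codes[["BLEACHED"]]))
  # OFF molecules under a bleach pulse never bleach directly
  off <- rep(fluor_codes[["OFF"]], 5000)
  s <- update_fluor(off, fluor_params(k_on_fluo = 0, k_bleach = 100), 0.1,
                    bleach_active = TRUE)
  expect_true(all(s == fluor_codes[["OFF"]]))
})

test_that("blinking equilibrium on-fraction is k_on/(k_on+k_off)", {
  set.seed(15)
  p <- fluor_params(k_on_fluo = 1, k_off_fluo = 3)
  s <- rep(fluor_codes[["OFF"]], 3000)
  for (i in 1:600) s <- update_fluor(s, p, 0.02)
  n_on <- sum(s == fluor_codes[["ON"]])
  expect_gt(binom.test(n_on, 3000, 0.25)$p.value, 0.01)
})

test_that("bleach monotonicity: the unbleached pool decays to zero", {
  set.seed(16)
  p <- fluor_params(k_on_fluo = 2, k_off_fluo = 2, k_bleach = 3)
  s <- rep(fluor_codes[["ON"]], 2000)
  alive_prev <- 2000
  for (i in 1:300) {
    s <- update_fluor(s, p, 0.05, bleach_active = TRUE)
    alive <- sum(s != fluor_codes[["BLEACHED"]])
    expect_lte(alive, alive_prev)
    alive_prev <- alive
  }
  expect_lt(alive_prev, 20)
})

test_that("activation is gated by the pulse and the PREACTIVE state", {
  p <- fluor_params(k_on_fluo = 0, k_activ = 100)
  pre <- rep(fluor_codes[["PREACTIVE"]], 1000)
  expect_true(all(update_fluor(pre, p, 1, activ_active = FALSE) ==
                  fluor_codes[["PREACTIVE"]]))
  set.seed(17)
  expect_true(all(update_fluor(pre, p, 1, activ_active = TRUE) ==
                  fluor_codes[["OFF"]])) # 1 - exp(-100) ~ 1
})

test_that("simulate_blink_trace: degenerate and renewal statistics", {
  p0 <- fluor_params(k_on_fluo = 0, k_off_fluo = 9.3)
  tr <- simulate_blink_trace(p0, 100, 0.02, initial = "off")
  expect_true(all(tr$on == 0))

  # burst count over T ~ k_on * T when k_on << k_off (renewal oracle: cycle
  # time 1/k_on + 1/k_off, bursts = T / cycle = 9.55 for the dSTORM rates)
  set.seed(18)
  p <- fluor_params(k_on_fluo = 0.006, k_off_fluo = 9.3)
  n_bursts <- replicate(150, nrow(attr(simulate_blink_trace(p, 1600, 0.02),
                                       "bursts")))
  cycle <- 1 / 0.006 + 1 / 9.3
  expect_within(mean(n_bursts), 1600 / cycle, 0.08)

  # on-frames per molecule: occupancy x frames = T k_on/(k_on+k_off)/dt
  set.seed(19)
  on_frames <- replicate(150, sum(simulate_blink_trace(p, 1600, 0.02)$on))
  expect_within(mean(on_frames), 1600 * (0.006 / 9.306) / 0.02, 0.10) # 51.6
})

test_that("fit_blinking_rates: exact dwells, round trip, degenerate input", {
  # alternating 2 frames on / 8 frames off at dt = 0.1 -> (1.25, 5.0)
  trace <- rep(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0), 40)
  fit <- fit_blinking_rates(trace, 0.1)
  expect_equal(unname(fit), c(1.25, 5.0))

  set.seed(20)
  p <- fluor_params(k_on_fluo = 0.006, k_off_fluo = 9.3)
  tr <- simulate_blink_trace(p, 1e5, 0.005)
  fit <- fit_blinking_rates(tr, 0.005)
  expect_within(fit[["k_on_fluo"]], 0.006, 0.10)
  expect_within(fit[["k_off_fluo"]], 9.3, 0.10)

  expect_error(fit_blinking_rates(rep(1, 100), 0.1), "dwell")
  expect_error(fit_blinking_rates(c(0, 1, 1, 0), 0.1), "uncensored")
})

test_that("event-based and per-step photophysics agree in dwell law", {
  # ON dwell times from the per-step chain vs the exponential law sampled
  # by the event engine (KS test); dt << 1/k_off_fluo
  set.seed(22)
  k_off <- 2
  p <- fluor_params(k_on_fluo = 5, k_off_fluo = k_off)
  dt <- 0.01
  s <- rep(fluor_codes[["ON"]], 400)
  dwell <- numeric(400)
  active <- rep(TRUE, 400)
  while (any(active)) {
    s <- update_fluor(s, p, dt)
    dwell[active] <- dwell[active] + dt
    active <- active & s == fluor_codes[["ON"]]
  }
  ks <- suppressWarnings(ks.test(dwell, "pexp", rate = k_off))
  expect_gt(ks$p.value, 0.01)
})
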