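test_that("sample_displacement has the Brownian moments", {
  expect_error(sample_displacement(-0.1, 0.02, 10), ">= 0")
  expect_equal(sample_displacement(0, 0.02, 5), matrix(0, 5, 2))
  set.seed(2)
  d <- sample_displacement(0.3, 0.02, 1e5)
  r2 <- mean(d[, 1]^2 + d[, 2]^2)
  expect_within(r2, 4 * 0.3 * 0.02, 0.02)          # 0.024 um^2
  expect_within(sd(d[, 1]), sqrt(2 * 0.3 * 0.02), 0.01)  # 0.1095 um
})

test_that("effective_D resolves state and region to the canonical values", {
  g <- fixture_two_region()
  m <- molecule_state(x = c(2, 10, 10), y = c(2, 10, 10),
                      bound = c(FALSE, FALSE, TRUE), region = c(0L, 1L, 1L))
  expect_equal(effective_D(m, g), c(0.3, 0.3, 0.04))
  # D invariant to crossing when D_in = D_out (free molecules)
  expect_equal(effective_D(m, g)[1], effective_D(m, g)[2])
})

test_that("update_binding follows first-order kinetics", {
  set.seed(3)
  n <- 2e5
  b <- update_binding(rep(FALSE, n), rep(TRUE, n), 0.15, 0.015, 0.02)
  p <- 1 - exp(-0.15 * 0.02)                        # 0.0029955
  expect_gt(binom.test(sum(b), n, p)$p.value, 0.01)
  # free outside the trap region never binds
  expect_false(any(update_binding(rep(FALSE, 1e4), FALSE, 10, 0, 0.02)))
  expect_error(update_binding(FALSE, TRUE, -1, 0, 0.02))
})

test_that("two-state occupancy converges to k_on/(k_on+k_off)", {
  set.seed(4)
  n <- 5000
  bound <- rep(FALSE, n)
  for (i in 1:1500) bound <- update_binding(bound, TRUE, 0.15, 0.015, 0.1)
  p <- 0.15 / 0.165                                 # 0.9091
  expect_gt(binom.test(sum(bound), n, p)$p.value, 0.01)
})

test_that("step_all: frozen dynamics are invariant, MSD is 4Ddt", {
  g <- fixture_two_region(D_out = 0, D_in = 0, D_trap = 0, k_on = 0, k_off = 0)
  set.seed(6)
  m0 <- initialize_positions(100, g)
  m <- m0
  for (i in 1:20) m <- step_all(m, g, 0.02)
  expect_identical(m$x, m0$x)
  expect_identical(m$y, m0$y)
  expect_identical(m$bound, m0$bound)

  # ensemble MSD linearity over lags 1..10 in a large free region
  set.seed(7)
  g2 <- fixture_free(cell = c(200, 200))
  m <- initialize_positions(3000, g2)
  x0 <- m$x; y0 <- m$y
  for (k in 1:10) {
    m <- step_all(m, g2, 0.02)
    msd <- mean((m$x - x0)^2 + (m$y - y0)^2)
    expect_within(msd, 4 * 0.3 * 0.02 * k, 0.08)
  }
})

test_that("step_all is deterministic under a fixed seed", {
  g <- fixture_two_region()
  run <- function() {
    set.seed(99)
    m <- initialize_positions(200, g)
    for (i in 1:50) m <- step_all(m, g, 0.02)
    m
  }
  expect_identical(run(), run())
})

test_that("initialize_positions: uniformity and FRAP-scale placement", {
  set.seed(8)
  g <- fixture_free(cell = c(20, 10))
  m <- initialize_positions(20000, g)
  left <- sum(m$x < 10)
  expect_gt(binom.test(left, 20000, 0.5)$p.value, 0.01)
  # population-scale placement completes
  big <- initialize_positions(150000, g)
  expect_equal(nrow(big), 150000)
  expect_true(all(point_in_region(cbind(big$x, big$y), g$cell_outline)))
})

test_that("equilibrated initialization approaches trapping equilibrium", {
  set.seed(42)
  # binding fast relative to diffusion across the contact, so the interior
  # occupancy is close to the pure two-state value k_on/(k_on+k_off) = 10/11
  g <- make_fixture_geometry(cell = c(14, 14),
                             contact = list(center = c(7, 7), radius = 3.5),
                             k_on = 0.6, k_off = 0.06, P_crossing = 1)
  m <- initialize_positions(1500, g, mode = "equilibrated",
                            warmup_steps = 1200, dt = 0.1)
  expect_within(mean(m$bound[m$region == 1L]), 10 / 11, 0.03)
})

test_that("trapped molecules are confined to their trapping region", {
  set.seed(12)
  g <- fixture_two_region(P_crossing = 1, k_on = 1e6, k_off = 0, D_trap = 3)
  m <- initialize_positions(300, g)
  inside0 <- m$region == 1L
  for (i in 1:40) m <- step_all(m, g, 0.05)  # trapped steps ~0.77 um
  # molecules that started inside bound immediately and can never leave
  expect_true(all(m$region[inside0] == 1L))
  expect_true(all(m$bound[inside0]))
})

test_that("simulate_free_trajectories has exact frame bookkeeping", {
  set.seed(13)
  tr <- simulate_free_trajectories(3, 50, 0.1, 0.02)
  expect_length(tr, 3)
  expect_equal(nrow(tr[[1]]), 51)
  expect_equal(tr[[2]]$frame, 1:51)
  expect_equal(tr[[3]]$x[1], 0)
})
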