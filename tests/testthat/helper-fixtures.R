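# Shared fixtures: geometries and small simulations built in code.

# 20 x 20 um rectangular cell with a centred circular contact of radius 5.
fixture_two_region <- function(P_crossing = 0.3, k_on = 0.15, k_off = 0.015,
                               D_out = 0.3, D_in = 0.3, D_trap = 0.04) {
  make_fixture_geometry(cell = c(20, 20),
                        contact = list(center = c(10, 10), radius = 5),
                        D_out = D_out, D_in = D_in, D_trap = D_trap,
                        k_on = k_on, k_off = k_off, P_crossing = P_crossing)
}

# Uniform rectangle with no contact (free pool).
fixture_free <- function(cell = c(20, 20), D = 0.3)
  make_fixture_geometry(cell = cell, contact = NULL, D_out = D)

# A square region occupying the left half of [0, 2] x [0, 1].
fixture_half_square <- function()
  region("half", rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
         kind = "generic_roi")

expect_within <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected), rel_tol * abs(expected))
}

default_config_for_test <- function() smfsim:::default_config()
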