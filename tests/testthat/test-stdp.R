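test_that("learning-rate profiles match their defining forms", {
  ar <- stdp_config("AR")
  sr <- stdp_config("SR")
  hy <- stdp_config("HYBRID", alpha = 0.5)

  expect_equal(learning_rate(0.3, "LTP", ar), 0.7)
  expect_equal(learning_rate(0.3, "LTD", ar), 0.3)
  expect_equal(learning_rate(0.5, "LTP", sr), 1.0)
  expect_equal(learning_rate(0.5, "LTD", sr), 1.0)
  expect_equal(learning_rate(0.0, "LTP", sr), 0.0)
  expect_equal(learning_rate(1.0, "LTD", sr), 0.0)
  # hybrid is the convex combination: 0.5 * 0.6 + 0.5 * 0.7
  expect_equal(learning_rate(0.3, "LTP", hy), 0.65)

  w <- seq(0, 1, by = 0.01)
  for (cfg in list(ar, sr, hy)) {
    expect_true(all(learning_rate(w, "LTP", cfg) >= 0))
    expect_true(all(learning_rate(w, "LTD", cfg) >= 0))
    # continuity: no jump larger than the Lipschitz bound over the grid
    expect_lt(max(abs(diff(learning_rate(w, "LTP", cfg)))), 0.021)
  }
  # SR symmetry about the mid-point
  expect_equal(learning_rate(w, "LTP", sr), learning_rate(1 - w, "LTP", sr))

  # hybrid endpoints reproduce the pure rules bit for bit
  expect_identical(learning_rate(w, "LTP", stdp_config("HYBRID", alpha = 0)),
                   learning_rate(w, "LTP", ar))
  expect_identical(learning_rate(w, "LTD", stdp_config("HYBRID", alpha = 1)),
                   learning_rate(w, "LTD", sr))

  expect_error(learning_rate(1.2, "LTP", ar), "outside")
  expect_error(stdp_config("AR", k_plus = -1))
  expect_error(stdp_config("HYBRID", alpha = 1.5))
})

test_that("kernel gives exponentially decaying LTP/LTD with dt = 0 as LTD", {
  ar <- stdp_config("AR")
  expect_equal(kernel_delta_w(3, 0.5, ar), 0.5 * 0.06 * exp(-1))
  expect_equal(kernel_delta_w(-15, 0.5, ar), 0.5 * (-0.09) * exp(-1))
  # saturation at the upper bound kills LTP in both profiles
  expect_equal(kernel_delta_w(3, 1, ar), 0)
  expect_equal(kernel_delta_w(3, 1, stdp_config("SR")), 0)
  # coincident pair falls in the depression branch
  expect_lt(kernel_delta_w(0, 0.5, ar), 0)
  # magnitude decays with |dt| on both sides
  d <- kernel_delta_w(c(1, 5, 20), 0.5, ar)
  expect_true(all(diff(abs(d)) < 0))
  d <- kernel_delta_w(-c(1, 5, 20), 0.5, ar)
  expect_true(all(diff(abs(d)) < 0))
})

test_that("clipped kernel application never leaves the weight bounds", {
  cfgeach <- list(stdp_config("AR"), stdp_config("SR"),
                  stdp_config("HYBRID", alpha = 0.3))
  set.seed(101)
  n <- 4e5  # x 3 profiles with both signs of dt mixed: > 1e6 updates total
  for (cfg in cfgeach) {
    dtv <- runif(n, -300, 300)
    w <- runif(n)
    w2 <- pmin(pmax(w + kernel_delta_w(dtv, w, cfg), cfg$w_min), cfg$w_max)
    expect_true(all(w2 >= cfg$w_min & w2 <= cfg$w_max))
  }
})

test_that("instability is the sum of squared learning rates", {
  expect_equal(instability(0.5, stdp_config("AR")), 0.5)
  expect_equal(instability(0.5, stdp_config("SR")), 2)
  expect_equal(instability(0, stdp_config("SR")), 0)
  expect_equal(instability(1, stdp_config("SR")), 0)
})

test_that("Boltzmann density normalises and has the profile's modal structure", {
  ar <- boltzmann_density(stdp_config("AR"), beta = 8, n_grid = 401)
  sr <- boltzmann_density(stdp_config("SR"), beta = 8, n_grid = 401)
  tz <- function(d) sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_equal(tz(ar), 1, tolerance = 1e-6)
  expect_equal(tz(sr), 1, tolerance = 1e-6)
  expect_true(all(ar$density >= 0))
  # asymmetric profile: unique interior maximum at the mid-point
  expect_equal(ar$grid[which.max(ar$density)], 0.5)
  # symmetric profile: maxima at both bounds, minimum mid-range
  expect_equal(max(sr$density), sr$density[1])
  expect_equal(sr$density[1], sr$density[401])
  expect_equal(sr$grid[which.min(sr$density)], 0.5)
  # mirror symmetry on a symmetric grid
  expect_equal(sr$density, rev(sr$density), tolerance = 1e-12)
  # vanishing inverse temperature flattens the density
  flat <- boltzmann_density(stdp_config("SR"), beta = 1e-12, n_grid = 11)
  expect_equal(max(flat$density) - min(flat$density), 0, tolerance = 1e-9)
  expect_error(boltzmann_density(stdp_config("AR"), beta = 0), "beta")
})

test_that("single-synapse trials are seeded, independent and silent at rate 0", {
  cfg <- stdp_config("SR")
  w1 <- simulate_single_synapse(cfg, duration = 10, rate = 10,
                                n_trials = 50, seed = 7)
  w2 <- simulate_single_synapse(cfg, duration = 10, rate = 10,
                                n_trials = 50, seed = 7)
  expect_identical(w1, w2)
  expect_true(all(w1 >= 0 & w1 <= 1))
  # with no spikes the final weight is the uniform-random initial weight
  w0 <- simulate_single_synapse(cfg, duration = 10, rate = 0,
                                n_trials = 10, seed = 3)
  initial <- local({ set.seed(3); runif(10) })
  expect_identical(w0, initial)
  expect_error(simulate_single_synapse(cfg, rate = 2000, dt = 1), "exceeds 1")
})
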