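test_that("network construction honours probability, weights and seed", {
  # degenerate draw: fully connected, all weights exactly the mean
  net <- build_network(10, 8, p_connect = 1, w_mean = 0.5, w_sd = 0, seed = 1)
  expect_true(all(net$mask == 1L))
  expect_true(all(net$W == 0.5))

  # connection count within the binomial 99.9% interval
  net <- build_network(50, 50, p_connect = 0.2, seed = 5)
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 2500, 0.2)
  expect_gte(sum(net$mask), bounds[1])
  expect_lte(sum(net$mask), bounds[2])
  expect_true(all(net$W[net$mask == 1L] >= 0 & net$W[net$mask == 1L] <= 1))
  expect_true(all(net$W[net$mask == 0L] == 0))

  # determinism
  net2 <- build_network(50, 50, p_connect = 0.2, seed = 5)
  expect_identical(net$mask, net2$mask)
  expect_identical(net$W, net2$W)

  expect_error(build_network(0, 10), "positive")
  expect_error(lif_params(E_threshold = -70))  # must sit between E_L and E_syn
})

test_that("single Euler step reproduces the hand-computed updates", {
  net <- build_network(5, 3, p_connect = 1, w_sd = 0,
                       params = lif_params(noise_sigma = 0), seed = 1)
  st <- lif_state(3, net$params)

  # resting fixed point with no input and no noise
  out <- lif_step(st, net, rep(0, 5))
  expect_equal(out$state$V, rep(-65, 3))
  expect_equal(out$spikes, rep(0L, 3))

  # conductance decay: 0.12 * (1 - 1/3) = 0.08
  st$g <- rep(0.12, 3)
  out <- lif_step(st, net, rep(0, 5))
  expect_equal(out$state$g, rep(0.08, 3))
  # voltage update sees the step-start conductance: -65 + 0.12 * 60 = -57.8
  expect_equal(out$state$V, rep(-57.8, 3))

  # threshold crossing spikes and resets within the step
  st$V <- rep(-55.5, 3); st$g <- rep(0.2, 3)
  out <- lif_step(st, net, rep(0, 5))
  expect_equal(out$spikes, rep(1L, 3))
  expect_equal(out$state$V, rep(-65, 3))

  expect_error(lif_step(structure(list(V = c(NaN, -65, -65), g = rep(0, 3)),
                                  class = "lif_state"),
                        net, rep(0, 5)), "finite")
})

test_that("frozen runs leave weights untouched and are deterministic", {
  net <- tiny_network(20, 15, "SR", seed = 11)
  input <- random_raster(20, 400, 60)
  r1 <- run_network(net, input, plastic = FALSE, seed = 21)
  r2 <- run_network(net, input, plastic = FALSE, seed = 21)
  expect_identical(net$W, r1$network$W)
  expect_identical(r1$output, r2$output)

  # silent input with no membrane noise stays silent
  net0 <- build_network(10, 10, params = lif_params(noise_sigma = 0), seed = 2)
  empty <- spike_trains(integer(0), integer(0), 10, 200)
  r <- run_network(net0, empty, plastic = TRUE)
  expect_identical(n_spikes(r$output), 0L)
  expect_identical(r$network$W, net0$W)
})

test_that("EPSP deflection from rest scales linearly with the synaptic weight", {
  # at rest the synaptic driving force is exactly E_syn - E_L, so the
  # voltage deflection on the step after a single input spike is exactly
  # proportional to w (the conductance-based peak saturates mildly later,
  # as the rising voltage reduces the driving force)
  epsp_onset <- function(w) {
    net <- build_network(1, 1, p_connect = 1, w_mean = w, w_sd = 0,
                         params = lif_params(noise_sigma = 0))
    st <- lif_state(1, net$params)
    st <- lif_step(st, net, 1L)$state   # spike arrives: g charges
    st <- lif_step(st, net, 0L)$state   # voltage feels the conductance
    st$V + 65
  }
  expect_equal(epsp_onset(0.5) / epsp_onset(0.25), 2, tolerance = 1e-9)
})

test_that("compiled runs agree with the R reference step-by-step", {
  net <- tiny_network(12, 9, "SR", seed = 3)
  input <- random_raster(12, 300, 80)
  seed <- 77
  cppr <- run_network(net, input, plastic = FALSE, seed = seed)
  R <- as_raster_matrix(input)
  st <- lif_state(9, net$params)
  spikes <- matrix(0L, 9, 300)
  set.seed(seed)
  for (t in 1:300) {
    out <- lif_step(st, net, R[, t])
    st <- out$state
    spikes[, t] <- out$spikes
  }
  expect_equal(as_raster_matrix(cppr$output), spikes)
})

test_that("carried state makes sliced runs identical to one long run", {
  net <- tiny_network(15, 12, "AR", seed = 8)
  input <- random_raster(15, 600, 120)
  whole <- run_network(net, input, plastic = TRUE, seed = 5)
  set.seed(5)
  a <- run_network(net, slice_spike_trains(input, 0, 250), plastic = TRUE)
  b <- run_network(a$network, slice_spike_trains(input, 250, 350),
                   plastic = TRUE, state = a$state)
  expect_identical(whole$network$W, b$network$W)
  expect_identical(whole$state, b$state)
})

test_that("weights stay inside bounds after long plastic runs", {
  net <- tiny_network(25, 20, "HYBRID", alpha = 0.4, seed = 13)
  input <- poisson_train(25, 20, 20, seed = 6)
  r <- run_network(net, input, plastic = TRUE, seed = 14)
  on_mask <- r$network$W[net$mask == 1L]
  expect_true(all(on_mask >= 0 & on_mask <= 1))
  expect_true(all(r$network$W[net$mask == 0L] == 0))
})
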