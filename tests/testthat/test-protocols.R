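# protocol tests run on a reduced geometry (fewer neurons, short sessions)
# so the whole file stays in the seconds range
small_args <- list(n_in = 20L, n_out = 20L, window = 50L, n_probe_trials = 10L)

test_that("training runs the expected repetitions and zero duration is a no-op", {
  net <- build_network(20, 20, seed = 1,
                       params = lif_params(), stdp = stdp_config("SR"))
  pat <- make_pattern(20, 50, seed = 2)
  expect_identical(train(net, pat, 0), net)
  expect_error(train(net, pat, 0.025), "whole number")
  trained <- train(net, pat, 5, seed = 3)
  expect_false(identical(trained$W, net$W))
  expect_identical(trained$mask, net$mask)
})

test_that("tests are read-only and deterministic without noise", {
  net0 <- build_network(20, 20, seed = 4,
                        params = lif_params(noise_sigma = 0),
                        stdp = stdp_config("AR"))
  pat <- make_pattern(20, 50, seed = 5)
  r1 <- test_memory(net0, pat, n_trials = 10)
  r2 <- test_memory(net0, pat, n_trials = 10)
  expect_identical(attr(r1, "responses"), attr(r2, "responses"))
  expect_identical(r1$mi, r2$mi)
  expect_identical(test_memory(net0, pat, n_trials = 2)$n_pair, 1)
})

test_that("trained patterns are recalled more consistently than fresh ones", {
  d <- train_test_experiment("SR", train_s = 20, n_networks = 4, seed = 1,
                             net_args = small_args)
  expect_identical(nrow(d), 4L)
  expect_true(all(d$mi_trained > d$mi_untrained))
})

test_that("decay bookkeeping: times, ratio, and the quiet-network limit", {
  # no background noise and no membrane noise: nothing perturbs the weights;
  # dense strong connectivity so the deterministic network is not silent
  quiet_args <- c(small_args, list(p_connect = 1, w_mean = 0.95, w_sd = 0))
  quiet <- decay_experiment("SR", train_s = 10, decay_s = 40, noise_rate = 0,
                            probe_every = 20, ratio_at = 40, n_networks = 2,
                            seed = 3, params = lif_params(noise_sigma = 0),
                            net_args = quiet_args)
  expect_true(all(quiet$ratios$ratio == 1))
  byseed <- split(quiet$mi_series$mi, quiet$mi_series$seed)
  for (mi in byseed) expect_true(all(mi == mi[1]))
  expect_identical(sort(unique(quiet$mi_series$time_s)), c(0, 20, 40))
  expect_error(decay_experiment("SR", decay_s = 50, probe_every = 20,
                                n_networks = 1, net_args = small_args),
               "multiple")
})

test_that("probe cadence never alters the plastic trajectory", {
  a <- decay_experiment("AR", train_s = 10, decay_s = 60, probe_every = 20,
                        ratio_at = 60, n_networks = 2, seed = 11,
                        net_args = small_args)
  b <- decay_experiment("AR", train_s = 10, decay_s = 60, probe_every = 60,
                        ratio_at = 60, n_networks = 2, seed = 11,
                        net_args = small_args)
  # with extra intermediate probes, the t=0 and t=60 probes are unchanged
  expect_identical(a$ratios$mi_start, b$ratios$mi_start)
  expect_identical(a$ratios$mi_end, b$ratios$mi_end)
})

test_that("appending probes every trained pattern plus an untrained baseline", {
  r <- append_experiment("SR", n_patterns = 2, durations = c(20, 40),
                         probe_every = 20, ratio_after = 20, n_networks = 2,
                         seed = 7, net_args = small_args)
  s <- r$mi_series
  expect_setequal(unique(s$pattern_id), c("P1", "P2", "untrained"))
  # P2 is only probed once its training has started
  expect_identical(sort(unique(s$time_s[s$pattern_id == "P2"])), c(40, 60))
  expect_identical(sort(unique(s$time_s[s$pattern_id == "P1"])), c(20, 40, 60))
  expect_identical(nrow(r$ratios), 2L)
  expect_true(all(r$mi_series$mi >= 0 & r$mi_series$mi <= 1))
  expect_true(all(diff(r$convergence$time_s[r$convergence$seed ==
                                              r$convergence$seed[1]]) > 0))
})

test_that("a single-pattern append schedule matches the decay bookkeeping", {
  # one pattern, no appending: the P1 series is just train + probes
  r <- append_experiment("AR", n_patterns = 1, durations = 20,
                         probe_every = 20, n_networks = 1, seed = 5,
                         net_args = small_args)
  expect_identical(unique(r$mi_series$pattern_id[r$mi_series$pattern_id != "untrained"]),
                   "P1")
})

test_that("hybrid sweep pairs seeds across alpha and honours the endpoints", {
  sw <- hybrid_sweep(c(0, 1), "decay", n_networks = 2, seed = 9,
                     train_s = 10, decay_s = 20, probe_every = 20,
                     ratio_at = 20, net_args = small_args)
  ar <- decay_experiment("AR", train_s = 10, decay_s = 20, probe_every = 20,
                         ratio_at = 20, n_networks = 2, seed = 9,
                         net_args = small_args)
  sr <- decay_experiment("SR", train_s = 10, decay_s = 20, probe_every = 20,
                         ratio_at = 20, n_networks = 2, seed = 9,
                         net_args = small_args)
  expect_identical(unname(sw$ratios[, "0"]), ar$ratios$ratio)
  expect_identical(unname(sw$ratios[, "1"]), sr$ratios$ratio)
})

test_that("output-pattern clones are identical without noise on a shared input", {
  r <- output_pattern_study(n_inputs = 3, train_s = 10, seed = 2,
                            params = lif_params(noise_sigma = 0),
                            model = "SR", net_args = small_args)
  expect_true(all(r$same == 1))
})
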