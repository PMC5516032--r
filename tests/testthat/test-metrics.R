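test_that("responses binarize per trial regardless of spike counts", {
  # neuron 2 spikes three times in trial 4 -> single 1; others stay 0
  out <- spike_trains(c(2L, 2L, 2L), c(310L, 350L, 399L), 5, 2000)
  S <- binarize_responses(out, 100, 20)
  expect_identical(dim(S), c(20L, 5L))
  expect_identical(S[4, 2], 1L)
  expect_identical(sum(S), 1L)

  silent <- spike_trains(integer(0), integer(0), 5, 600)
  expect_true(all(binarize_responses(silent, 100, 6) == 0L))

  dense <- tile_pattern(make_pattern(5, 100, seed = 1), 6)
  expect_true(all(binarize_responses(dense, 100, 6) == 1L))

  expect_error(binarize_responses(silent, 100, 7), "length")
})

test_that("memory index matches its defining formula and conventions", {
  # twenty identical vectors with 10 active neurons: perfect consistency
  S <- matrix(0L, 20, 50); S[, 1:10] <- 1L
  r <- memory_index(S)
  expect_equal(r$mi, 1)
  expect_identical(r$n_pair, 190)
  expect_identical(r$n_firing, 10L)

  # pairwise-disjoint single-neuron responses: no overlap at all
  D <- diag(1L, 20, 50)
  expect_equal(memory_index(D)$mi, 0)

  # silent set returns 0 by convention
  expect_equal(memory_index(matrix(0L, 20, 50))$mi, 0)

  expect_identical(memory_index(matrix(c(0L, 1L), 2, 1))$n_pair, 1)
})

test_that("memory index equals the naive double-loop oracle exactly", {
  set.seed(42)
  for (rep in 1:100) {
    S <- matrix(rbinom(20 * 30, 1, runif(1, 0.05, 0.9)), 20, 30)
    expect_identical(memory_index(S)$mi, ref_memory_index(S))
  }
})

test_that("memory index is invariant to trial and neuron permutations, and bounded", {
  set.seed(7)
  for (rep in 1:200) {
    S <- matrix(rbinom(20 * 40, 1, runif(1, 0, 1)), 20, 40)
    mi <- memory_index(S)$mi
    expect_gte(mi, 0); expect_lte(mi, 1)
    expect_equal(memory_index(S[sample(20), ])$mi, mi)
    expect_equal(memory_index(S[, sample(40)])$mi, mi)
  }
})

test_that("maintained ratio divides end by start and rejects zero start", {
  expect_equal(maintained_ratio(0.5, 0.5), 1)
  expect_equal(maintained_ratio(0.8, 0.2), 0.25)
  expect_error(maintained_ratio(0, 0.5), "> 0")
})

test_that("output pattern uses a strict threshold and correlations behave", {
  S <- matrix(0L, 20, 3)
  S[1:17, 1] <- 1L  # 17/20 > 16: included
  S[1:16, 2] <- 1L  # 16/20 is not strictly above 0.8: excluded
  expect_identical(output_pattern(S, 0.8), c(1L, 0L, 0L))
  expect_identical(output_pattern(matrix(1L, 20, 4)), rep(1L, 4))

  a <- c(1, 0, 1, 0, 1)
  expect_equal(pattern_correlation(a, a), 1)
  expect_equal(pattern_correlation(a, 1 - a), -1)
  expect_error(pattern_correlation(a, rep(1, 5)), "constant")
})

test_that("convergence ratio counts weights near the bounds", {
  mask <- matrix(1L, 4, 4)
  expect_equal(convergence_ratio(matrix(0.5, 4, 4), mask, eps = 0.1), 0)
  W <- matrix(rep(c(0, 1), 8), 4, 4)
  expect_equal(convergence_ratio(W, mask, eps = 0.1), 1)
  W[1, 1] <- 0.5
  expect_equal(convergence_ratio(W, mask, eps = 0.1), 15 / 16)
  expect_error(convergence_ratio(W, mask, eps = 0.6), "eps")
})
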