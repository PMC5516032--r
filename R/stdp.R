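#' STDP configuration with a weight-dependent learning-rate profile
#'
#' Pair-based STDP kernel: a pre-before-post spike pair separated by
#' `dt > 0` potentiates by `eps_plus(w) * k_plus * exp(-dt / tau_plus)`;
#' a post-before-pre pair (`dt <= 0`, including coincident spikes)
#' depresses by `eps_minus(w) * k_minus * exp(-|dt| / tau_minus)`.
#' The weight-dependent rates `eps` come in three profiles:
#'
#' * `"AR"` (asymmetric rate, the multiplicative rule):
#'   `eps_plus = w_max - w`, `eps_minus = w - w_min`.  Weak synapses
#'   potentiate easily, strong ones depress easily; the stable weight is
#'   mid-range.
#' * `"SR"` (symmetric rate): `eps = 2 * min(w_max - w, w - w_min)` for both
#'   directions.  Plasticity peaks at mid-range and vanishes at the bounds;
#'   weights are bistable at `w_min` and `w_max`.
#' * `"HYBRID"`: `alpha * SR + (1 - alpha) * AR`, elementwise in `w`.
#'
#' @param profile `"AR"`, `"SR"` or `"HYBRID"`.
#' @param alpha proportion of the symmetric rule in the hybrid mixture,
#'   in `[0, 1]`.  Ignored unless `profile = "HYBRID"`.
#' @param k_plus LTP amplitude (> 0).
#' @param k_minus LTD amplitude (< 0).
#' @param tau_plus,tau_minus LTP / LTD kernel decay constants (ms).
#' @param w_min,w_max weight bounds; weights are clipped to this interval
#'   after every update.
#' @param pairing_window horizon (ms) used by pair-based accounting of the
#'   kernel.  The simulator pairs all spikes through exponentially decaying
#'   traces, which is equivalent to all-to-all pairing; beyond
#'   `7 * max(tau_plus, tau_minus)` a pair's contribution is below `e^-7`.
#' @return an object of class `stdp_config`.
#' @examples
#' cfg <- stdp_config("SR")
#' learning_rate(0.5, "LTP", cfg)
#' @export
stdp_config <- function(profile = c("AR", "SR", "HYBRID"), alpha = 0.5,
                        k_plus = 0.06, k_minus = -0.09,
                        tau_plus = 3, tau_minus = 15,
                        w_min = 0, w_max = 1,
                        pairing_window = 7 * max(tau_plus, tau_minus)) {
  profile <- match.arg(profile)
  stopifnot(k_plus > 0, k_minus < 0, tau_plus > 0, tau_minus > 0,
            w_min < w_max, pairing_window > 0)
  if (profile == "HYBRID") {
    stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  }
  structure(
    list(profile = profile, alpha = if (profile == "HYBRID") alpha else NA_real_,
         k_plus = k_plus, k_minus = k_minus,
         tau_plus = tau_plus, tau_minus = tau_minus,
         w_min = w_min, w_max = w_max, pairing_window = pairing_window),
    class = "stdp_config")
}

#' @export
print.stdp_config <- function(x, ...) {
  mix <- if (x$profile == "HYBRID") sprintf(" (alpha = %g)", x$alpha) else ""
  cat(sprintf("STDP config: profile %s%s\n", x$profile, mix))
  cat(sprintf("  kernel: k+ = %g, k- = %g, tau+ = %g ms, tau- = %g ms\n",
              x$k_plus, x$k_minus, x$tau_plus, x$tau_minus))
  cat(sprintf("  weight bounds: [%g, %g]\n", x$w_min, x$w_max))
  invisible(x)
}

# effective SR proportion: AR == alpha 0, SR == alpha 1; the hybrid formula
# with these endpoints reproduces the pure rules exactly
stdp_alpha <- function(config) {
  switch(config$profile, AR = 0, SR = 1, HYBRID = config$alpha)
}

check_weights_in_bounds <- function(w, config) {
  if (any(w < config$w_min - 1e-12) || any(w > config$w_max + 1e-12))
    stop("weight outside [w_min, w_max]")
  invisible(TRUE)
}

#' Weight-dependent learning rate
#'
#' Evaluates the learning-rate profile of a [stdp_config()] at weight(s)
#' `w` for the given plasticity direction.  For `"HYBRID"` this is
#' `alpha * eps_SR + (1 - alpha) * eps_AR`.
#'
#' @param w weight value(s) in `[w_min, w_max]`.
#' @param direction `"LTP"` or `"LTD"`.
#' @param config an [stdp_config()].
#' @return nonnegative rate value(s), same length as `w`.
#' @export
learning_rate <- function(w, direction = c("LTP", "LTD"), config) {
  direction <- match.arg(direction)
  check_weights_in_bounds(w, config)
  a <- stdp_alpha(config)
  sr <- 2 * pmin(config$w_max - w, w - config$w_min)
  ar <- if (direction == "LTP") config$w_max - w else w - config$w_min
  a * sr + (1 - a) * ar
}

#' STDP kernel: weight change for one spike pair
#'
#' `delta_t = t_post - t_pre` in ms.  `delta_t > 0` is the LTP branch,
#' `delta_t <= 0` (including coincident spikes) the LTD branch; the
#' magnitude decays as `exp(-|delta_t| / tau)` in both branches.
#'
#' @param delta_t spike-time difference(s), ms.
#' @param w current weight(s).
#' @param config an [stdp_config()].
#' @return weight change(s); positive for LTP, nonpositive for LTD.
#' @examples
#' kernel_delta_w(3, 0.5, stdp_config("AR"))   # 0.5 * 0.06 * exp(-1)
#' @export
kernel_delta_w <- function(delta_t, w, config) {
  stopifnot(all(is.finite(delta_t)))
  check_weights_in_bounds(w, config)
  ltp <- delta_t > 0
  eps <- ifelse(ltp,
                learning_rate(w, "LTP", config),
                learning_rate(w, "LTD", config))
  k   <- ifelse(ltp, config$k_plus, config$k_minus)
  tau <- ifelse(ltp, config$tau_plus, config$tau_minus)
  eps * k * exp(-abs(delta_t) / tau)
}

#' Synaptic instability
#'
#' The expected squared weight change at weight `w`,
#' `eps_plus(w)^2 + eps_minus(w)^2`.  Minima of this functional are the
#' stable weights of the rule: mid-range for the asymmetric profile, the
#' two bounds for the symmetric profile.
#'
#' @inheritParams learning_rate
#' @return nonnegative value(s), same length as `w`.
#' @export
instability <- function(w, config) {
  learning_rate(w, "LTP", config)^2 + learning_rate(w, "LTD", config)^2
}

#' Boltzmann stationary-density predictor for the synaptic weight
#'
#' Treating the weight as a random walk driven by noisy spike pairings, the
#' stationary density is approximated by a Boltzmann distribution over the
#' instability functional, `p(w) ~ exp(-beta * instability(w))`, normalised
#' on `[w_min, w_max]`.  `beta` is a free inverse-temperature parameter; the
#' predictor is used for its modal structure (one mid-range mode for the
#' asymmetric profile, modes at both bounds for the symmetric profile), not
#' its exact shape.
#'
#' @param config an [stdp_config()].
#' @param beta inverse temperature, > 0.
#' @param n_grid number of grid points (>= 3).
#' @return an object of class `density_estimate`: list with `grid`,
#'   `density` (trapezoid-normalised) and `beta`.
#' @export
boltzmann_density <- function(config, beta = 8, n_grid = 201) {
  stopifnot(is.numeric(beta), length(beta) == 1L)
  if (beta <= 0) stop("beta must be > 0")
  stopifnot(n_grid >= 3)
  grid <- seq(config$w_min, config$w_max, length.out = n_grid)
  dens <- exp(-beta * instability(grid, config))
  z <- trapz(grid, dens)
  structure(list(grid = grid, density = dens / z, beta = beta),
            class = "density_estimate")
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Apply STDP updates for fixed pre- and postsynaptic rasters
#'
#' Replays the trace-based plasticity of [run_network()] against given
#' spike rasters, without membrane dynamics: exponentially decaying pre-
#' and postsynaptic traces implement all-to-all spike pairing; at each
#' presynaptic spike the connected weights are depressed in proportion to
#' the postsynaptic trace, at each postsynaptic spike they are potentiated
#' in proportion to the presynaptic trace, coincident (same-step) pairs
#' fall in the LTD branch, and every update is clipped to the weight
#' bounds.  Replaying the rasters recorded from a plastic [run_network()]
#' call reproduces that run's final weights exactly.
#'
#' @param network a [build_network()] object.
#' @param pre a [spike_trains()] raster over the input layer.
#' @param post a [spike_trains()] raster over the output layer, same
#'   length.
#' @return the network with updated weights.
#' @export
apply_stdp <- function(network, pre, post) {
  stopifnot(inherits(network, "feedforward_network"),
            inherits(pre, "spike_trains"), inherits(post, "spike_trains"),
            pre$n_neurons == network$n_in, post$n_neurons == network$n_out,
            pre$n_steps == post$n_steps)
  network$W <- cpp_stdp_trace(network$mask, network$W,
                              pre$neuron - 1L, pre$time,
                              post$neuron - 1L, post$time,
                              pre$n_steps, unclass(network$stdp),
                              stdp_alpha(network$stdp), network$params$dt)
  network
}

#' Monte-Carlo simulation of a single plastic synapse
#'
#' One presynaptic and one postsynaptic neuron fire independent Poisson
#' trains (per-ms Bernoulli thinning on the integration grid); every spike
#' pairing updates the weight through the STDP kernel with the configured
#' learning-rate profile, with clipping to the weight bounds.  Each trial
#' starts from an independent uniform-random weight in
#' `[w_min, w_max]` and runs for `duration` seconds; the final weight is
#' recorded.  The histogram of final weights estimates the stationary weight
#' density and can be compared with [boltzmann_density()].
#'
#' @param config an [stdp_config()].
#' @param duration trial duration in seconds.
#' @param rate Poisson firing rate of both neurons, Hz.
#' @param n_trials number of independent trials.
#' @param dt time step, ms.
#' @param seed optional integer seed; identical seeds give identical output.
#' @return numeric vector of `n_trials` final weights.
#' @export
simulate_single_synapse <- function(config, duration = 1000, rate = 10,
                                    n_trials = 10000, dt = 1, seed = NULL) {
  stopifnot(duration > 0, rate >= 0, n_trials > 0, dt > 0)
  p <- rate * dt / 1000
  if (p > 1) stop("rate * dt / 1000 exceeds 1: spike probability per step")
  n_steps <- as.integer(round(duration * 1000 / dt))
  with_seed(seed,
    cpp_single_synapse(as.integer(n_trials), n_steps, p,
                       unclass(config), stdp_alpha(config), dt))
}
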