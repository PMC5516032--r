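#' Spike trains as a sparse event list
#'
#' Container for a binary spike raster over `n_neurons` neurons and
#' `n_steps` ms-resolution time steps, stored sparsely as (neuron, time)
#' events.  Times are integer ms offsets in `[0, n_steps)`; neuron ids are
#' 1-based inside R (the CSV interface uses 0-based ids).
#'
#' @param neuron integer vector of 1-based neuron ids.
#' @param time integer vector of 0-based spike times (ms).
#' @param n_neurons,n_steps raster dimensions.
#' @return an object of class `spike_trains`, sorted by time then neuron.
#' @export
spike_trains <- function(neuron, time, n_neurons, n_steps) {
  stopifnot(length(neuron) == length(time), n_neurons >= 1, n_steps >= 0)
  neuron <- as.integer(neuron); time <- as.integer(time)
  if (length(neuron) && (min(neuron) < 1L || max(neuron) > n_neurons))
    stop("neuron id out of range")
  if (length(time) && (min(time) < 0L || max(time) >= n_steps))
    stop("spike time outside [0, n_steps)")
  ord <- order(time, neuron)
  structure(list(neuron = neuron[ord], time = time[ord],
                 n_neurons = as.integer(n_neurons),
                 n_steps = as.integer(n_steps)),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("spike_trains: %d neurons, %d ms, %d spikes\n",
              x$n_neurons, x$n_steps, length(x$neuron)))
  invisible(x)
}

#' Number of spikes in a raster
#' @param x a `spike_trains` object.
#' @return integer spike count.
#' @export
n_spikes <- function(x) length(x$neuron)

#' Densify a spike raster
#'
#' @param x a `spike_trains` object.
#' @return 0/1 integer matrix, `n_neurons` rows by `n_steps` columns.
#' @export
as_raster_matrix <- function(x) {
  m <- matrix(0L, x$n_neurons, x$n_steps)
  if (length(x$neuron)) m[cbind(x$neuron, x$time + 1L)] <- 1L
  m
}

#' Temporal input pattern: one spike per neuron in a fixed window
#'
#' Each of `n_neurons` input neurons fires exactly once, at an independent
#' uniform-random integer time in `[0, window)` ms.  With the default
#' 100-ms window this gives a per-neuron rate of 10 Hz when the pattern is
#' repeated back to back.
#'
#' @param n_neurons number of input neurons.
#' @param window pattern duration, ms (integer >= 1).
#' @param seed optional integer seed; identical seeds give identical
#'   patterns.
#' @return an object of class `input_pattern` with fields `n_neurons`,
#'   `window` and `spike_times` (0-based integer ms, one per neuron).
#' @export
make_pattern <- function(n_neurons = 50, window = 100, seed = NULL) {
  stopifnot(n_neurons >= 1, window >= 1)
  times <- with_seed(seed,
                     sample.int(as.integer(window), n_neurons,
                                replace = TRUE) - 1L)
  structure(list(n_neurons = as.integer(n_neurons),
                 window = as.integer(window),
                 spike_times = times),
            class = "input_pattern")
}

#' @export
print.input_pattern <- function(x, ...) {
  cat(sprintf("input_pattern: %d neurons, one spike each in [0, %d) ms\n",
              x$n_neurons, x$window))
  invisible(x)
}

#' Tile an input pattern into a back-to-back raster
#'
#' Repeats the pattern `n_reps` times with no gap: repetition `k`
#' (0-based) contains the pattern shifted by `k * window` ms.
#'
#' @param pattern an [make_pattern()] object.
#' @param n_reps number of repetitions (>= 1).
#' @return a [spike_trains()] raster of `n_reps * window` ms with
#'   `n_reps * n_neurons` spikes.
#' @export
tile_pattern <- function(pattern, n_reps) {
  stopifnot(inherits(pattern, "input_pattern"), n_reps >= 1)
  n_reps <- as.integer(n_reps)
  shifts <- rep((seq_len(n_reps) - 1L) * pattern$window,
                each = pattern$n_neurons)
  spike_trains(neuron = rep(seq_len(pattern$n_neurons), times = n_reps),
               time = rep(pattern$spike_times, times = n_reps) + shifts,
               n_neurons = pattern$n_neurons,
               n_steps = n_reps * pattern$window)
}

#' Homogeneous Poisson spike trains on the simulation grid
#'
#' Each neuron spikes independently in each `dt`-ms step with probability
#' `rate * dt / 1000` (Bernoulli thinning of a Poisson process on the
#' integration grid).  Spike times are generated by geometric gaps, which
#' is distributionally identical to per-step Bernoulli draws.
#'
#' @param n_neurons number of neurons.
#' @param rate firing rate, Hz (>= 0).
#' @param duration train duration, seconds.
#' @param dt time step, ms.
#' @param seed optional integer seed.
#' @return a [spike_trains()] raster of `duration * 1000 / dt` steps.
#' @export
poisson_train <- function(n_neurons, rate, duration, dt = 1, seed = NULL) {
  stopifnot(n_neurons >= 1, rate >= 0, duration >= 0, dt > 0)
  p <- rate * dt / 1000
  if (p > 1) stop("rate * dt / 1000 exceeds 1: spike probability per step")
  n_steps <- as.integer(round(duration * 1000 / dt))
  if (p == 0 || n_steps == 0L)
    return(spike_trains(integer(0), integer(0), n_neurons, n_steps))
  with_seed(seed, {
    nrn <- vector("list", n_neurons)
    tms <- vector("list", n_neurons)
    for (i in seq_len(n_neurons)) {
      t <- spike_times_geometric(n_steps, p)
      nrn[[i]] <- rep(i, length(t))
      tms[[i]] <- t
    }
    spike_trains(unlist(nrn), unlist(tms), n_neurons, n_steps)
  })
}

#' Extract a time slice of a spike raster
#'
#' @param x a [spike_trains()] object.
#' @param from first step of the slice (0-based, inclusive).
#' @param len slice length in steps.
#' @return a [spike_trains()] raster of `len` steps with times re-based to
#'   the slice start.
#' @export
slice_spike_trains <- function(x, from, len) {
  stopifnot(inherits(x, "spike_trains"), from >= 0, len >= 0,
            from + len <= x$n_steps)
  sel <- x$time >= from & x$time < from + len
  spike_trains(x$neuron[sel], x$time[sel] - as.integer(from),
               x$n_neurons, len)
}

# 0-based spike steps for one neuron: first spike at rgeom(p), then gaps of
# rgeom(p) + 1, truncated to [0, n_steps)
spike_times_geometric <- function(n_steps, p) {
  expected <- n_steps * p
  chunk <- max(16L, as.integer(ceiling(expected + 6 * sqrt(expected + 1))))
  t <- integer(0)
  last <- -1L
  repeat {
    gaps <- rgeom(chunk, p) + 1L
    new <- last + cumsum(gaps)
    t <- c(t, new)
    last <- t[length(t)]
    if (last >= n_steps) break
  }
  t[t < n_steps]
}
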