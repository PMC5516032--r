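#' Write / read spike rasters as sparse event CSV
#'
#' Columns `neuron_id,time_ms` with 0-based neuron ids and integer ms
#' times from session start.
#'
#' @param x a [spike_trains()] object.
#' @param path file path.
#' @param n_neurons,n_steps raster dimensions (required on read; the event
#'   list does not carry them).
#' @return `write_spike_trains` returns `path` invisibly;
#'   `read_spike_trains` returns a [spike_trains()] object.
#' @export
write_spike_trains <- function(x, path) {
  stopifnot(inherits(x, "spike_trains"))
  write.csv(data.frame(neuron_id = x$neuron - 1L, time_ms = x$time),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path, n_neurons, n_steps) {
  d <- read.csv(path)
  stopifnot(all(c("neuron_id", "time_ms") %in% names(d)))
  spike_trains(d$neuron_id + 1L, d$time_ms, n_neurons, n_steps)
}

#' Write / read an input pattern as CSV
#'
#' Same `neuron_id,time_ms` layout as rasters; exactly one row per neuron.
#'
#' @param pattern an [make_pattern()] object.
#' @param path file path.
#' @param window pattern window (ms), required on read.
#' @return `write_pattern` returns `path` invisibly; `read_pattern`
#'   returns an `input_pattern`.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "input_pattern"))
  write.csv(data.frame(neuron_id = seq_len(pattern$n_neurons) - 1L,
                       time_ms = pattern$spike_times),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path, window) {
  d <- read.csv(path)
  stopifnot(all(c("neuron_id", "time_ms") %in% names(d)))
  d <- d[order(d$neuron_id), ]
  if (!identical(as.integer(d$neuron_id), seq_len(nrow(d)) - 1L))
    stop("pattern file must contain exactly one row per neuron")
  structure(list(n_neurons = nrow(d), window = as.integer(window),
                 spike_times = as.integer(d$time_ms)),
            class = "input_pattern")
}

#' Write single-synapse final weights as CSV
#'
#' Single column with header `final_weight`, one row per trial.
#'
#' @param weights numeric vector from [simulate_single_synapse()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_final_weights <- function(weights, path) {
  write.csv(data.frame(final_weight = weights), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a memory-index series as CSV
#'
#' @param mi_series the `mi_series` data.frame of a `session_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mi_series <- function(mi_series, path) {
  write.csv(mi_series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
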