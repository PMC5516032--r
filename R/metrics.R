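#' Binary response vectors from repeated test trials
#'
#' Splits an output raster into `n_trials` consecutive windows of `window`
#' ms and records, per trial and neuron, whether the neuron fired at least
#' once in that window (multiple spikes still count as 1).
#'
#' @param output a [spike_trains()] raster over the output layer whose
#'   length equals `n_trials * window`.
#' @param window trial duration, ms.
#' @param n_trials number of repeated trials.
#' @return an object of class `response_set`: 0/1 integer matrix with
#'   `n_trials` rows and one column per neuron.
#' @export
binarize_responses <- function(output, window, n_trials) {
  stopifnot(inherits(output, "spike_trains"), window >= 1, n_trials >= 1)
  if (output$n_steps != n_trials * window)
    stop("raster length must equal n_trials * window")
  S <- matrix(0L, n_trials, output$n_neurons)
  if (length(output$neuron)) {
    trial <- output$time %/% as.integer(window) + 1L
    S[cbind(trial, output$neuron)] <- 1L
  }
  structure(S, class = c("response_set", class(S)))
}

#' Memory index: response consistency over repeated trials
#'
#' The memory index is the average pairwise dot product of the binary
#' response vectors, normalised by the number of responsive neurons:
#' `MI = (1 / N_pair) * sum_{m < n} (S_m . S_n) / N_firing`, where
#' `N_pair = n_trials * (n_trials - 1) / 2` and `N_firing` is the number of
#' neurons that fired at least once across all trials.  An all-silent
#' response set returns `MI = 0` by convention, so decay curves stay
#' defined if activity collapses.
#'
#' @param responses a [binarize_responses()] matrix (rows = trials).
#' @return an object of class `memory_index_result`: list with `mi`,
#'   `n_pair` and `n_firing`.
#' @export
memory_index <- function(responses) {
  S <- unclass(responses)
  n_trials <- nrow(S)
  stopifnot(n_trials >= 2)
  n_pair <- n_trials * (n_trials - 1) / 2
  n_firing <- sum(colSums(S) > 0)
  mi <- if (n_firing == 0) 0 else {
    G <- tcrossprod(S)  # trial-by-trial dot products
    sum(G[upper.tri(G)]) / n_firing / n_pair
  }
  structure(list(mi = mi, n_pair = n_pair, n_firing = n_firing),
            class = "memory_index_result")
}

#' @export
print.memory_index_result <- function(x, ...) {
  cat(sprintf("memory index: %.4f (%d pairs, %d responsive neurons)\n",
              x$mi, x$n_pair, x$n_firing))
  invisible(x)
}

#' Maintained memory ratio
#'
#' The memory index after a perturbation (decay or appending) divided by
#' the index before it; 1 means no loss.
#'
#' @param mi_start memory index before the perturbation (> 0).
#' @param mi_end memory index after.
#' @return `mi_end / mi_start`.
#' @export
maintained_ratio <- function(mi_start, mi_end) {
  if (inherits(mi_start, "memory_index_result")) mi_start <- mi_start$mi
  if (inherits(mi_end, "memory_index_result")) mi_end <- mi_end$mi
  if (mi_start <= 0) stop("mi_start must be > 0 for a defined ratio")
  mi_end / mi_start
}

#' Consistently responding neurons (output pattern)
#'
#' The set of output neurons that respond in strictly more than
#' `threshold * n_trials` of the test trials; the model's proxy for an
#' engram.
#'
#' @param responses a [binarize_responses()] matrix.
#' @param threshold required response fraction in (0, 1]; strict
#'   inequality, so 16/20 trials does not pass a 0.8 threshold but 17/20
#'   does.
#' @return 0/1 integer vector, one entry per neuron.
#' @export
output_pattern <- function(responses, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  S <- unclass(responses)
  as.integer(colSums(S) > threshold * nrow(S))
}

#' Pearson correlation between two binary patterns
#'
#' @param a,b 0/1 vectors of equal length; each must be non-constant.
#' @return Pearson correlation coefficient.
#' @export
pattern_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined for a constant pattern")
  cor(a, b)
}

#' Fraction of weights converged to a bound
#'
#' @param W weight matrix.
#' @param mask 0/1 connectivity mask of the same shape.
#' @param eps margin: a weight counts as converged when within `eps` of
#'   either bound; must satisfy `0 < eps < (w_max - w_min) / 2`.
#' @param w_min,w_max weight bounds.
#' @return fraction of masked weights at `<= w_min + eps` or
#'   `>= w_max - eps`.
#' @export
convergence_ratio <- function(W, mask, eps = 0.1, w_min = 0, w_max = 1) {
  stopifnot(eps > 0, eps < (w_max - w_min) / 2, all(dim(W) == dim(mask)))
  w <- W[mask == 1L]
  if (!length(w)) return(NaN)
  mean(w <= w_min + eps | w >= w_max - eps)
}
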