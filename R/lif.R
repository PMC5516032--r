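#' Leaky integrate-and-fire neuron parameters
#'
#' Membrane dynamics of output neuron `j`:
#' `C dV/dt = g_L (E_L - V) + g (E_syn - V) + I_noise`, with synaptic
#' conductance `dg/dt = -g / tau_syn + c_syn * sum_i w_ij S_i(t)`.
#' `I_noise` is an independent Gaussian current per neuron per step with
#' s.d. `noise_sigma`.  A neuron crossing `E_threshold` spikes immediately
#' and resets to `E_L` within the same step.  Parameters are treated as
#' dimensionless numbers in a consistent system with voltages in mV and
#' time in ms; the effective membrane time constant is `C / g_L` = 2.5 ms.
#'
#' @param C membrane capacitance.
#' @param g_L leak conductance.
#' @param E_L resting potential (mV).
#' @param E_syn synaptic reversal potential (mV).
#' @param E_threshold spike threshold (mV); must lie between `E_L` and
#'   `E_syn`.
#' @param tau_syn conductance decay constant (ms).
#' @param c_syn conductance increment per unit-weight input spike (per ms).
#' @param noise_sigma s.d. of the Gaussian noise current.
#' @param dt integration step (ms).
#' @return an object of class `lif_params`.
#' @export
lif_params <- function(C = 1, g_L = 0.4, E_L = -65, E_syn = -5,
                       E_threshold = -55, tau_syn = 3, c_syn = 0.12,
                       noise_sigma = 1.2, dt = 1) {
  stopifnot(dt > 0, tau_syn > 0, C > 0, g_L > 0, c_syn > 0,
            noise_sigma >= 0, E_L < E_threshold, E_threshold < E_syn)
  structure(list(C = C, g_L = g_L, E_L = E_L, E_syn = E_syn,
                 E_threshold = E_threshold, tau_syn = tau_syn,
                 c_syn = c_syn, noise_sigma = noise_sigma, dt = dt),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "LIF params: C=%g g_L=%g E_L=%g E_syn=%g E_thr=%g tau_syn=%g c_syn=%g sigma=%g dt=%g\n",
    x$C, x$g_L, x$E_L, x$E_syn, x$E_threshold, x$tau_syn, x$c_syn,
    x$noise_sigma, x$dt))
  invisible(x)
}

#' Fresh membrane state for a population
#'
#' @param n number of neurons.
#' @param params an [lif_params()].
#' @return an object of class `lif_state` with voltage `V` (at rest) and
#'   conductance `g` (zero).
#' @export
lif_state <- function(n, params) {
  structure(list(V = rep(params$E_L, n), g = rep(0, n)), class = "lif_state")
}

#' Sparse random feedforward network
#'
#' Each (input, output) pair is independently connected with probability
#' `p_connect`; the weights of existing connections are drawn from
#' `Normal(w_mean, w_sd)` and clipped to the STDP weight bounds.
#' Unconnected entries of the weight matrix are exactly zero and the
#' connectivity mask is fixed for the lifetime of the network.
#'
#' @param n_in,n_out layer sizes.
#' @param p_connect connection probability in (0, 1].
#' @param w_mean,w_sd initial-weight distribution parameters (`w_sd >= 0`).
#' @param params an [lif_params()].
#' @param stdp an [stdp_config()] governing plastic runs.
#' @param seed optional integer seed; identical seeds give identical
#'   mask and weights.
#' @return an object of class `feedforward_network` with fields `mask`
#'   (0/1 integer matrix, `n_in` x `n_out`), `W` (weights), `n_in`,
#'   `n_out`, `params`, `stdp`.
#' @export
build_network <- function(n_in = 50, n_out = 50, p_connect = 0.2,
                          w_mean = 0.5, w_sd = 0.05,
                          params = lif_params(), stdp = stdp_config("SR"),
                          seed = NULL) {
  if (n_in < 1 || n_out < 1) stop("layer sizes must be positive")
  stopifnot(p_connect > 0, p_connect <= 1, w_sd >= 0)
  with_seed(seed, {
    mask <- matrix(as.integer(runif(n_in * n_out) < p_connect), n_in, n_out)
    W <- matrix(0, n_in, n_out)
    idx <- which(mask == 1L)
    W[idx] <- pmin(pmax(rnorm(length(idx), w_mean, w_sd), stdp$w_min),
                   stdp$w_max)
    structure(list(mask = mask, W = W, n_in = as.integer(n_in),
                   n_out = as.integer(n_out), params = params, stdp = stdp),
              class = "feedforward_network")
  })
}

#' @export
print.feedforward_network <- function(x, ...) {
  cat(sprintf(
    "feedforward_network: %d -> %d neurons, %d connections (%s STDP)\n",
    x$n_in, x$n_out, sum(x$mask), x$stdp$profile))
  invisible(x)
}

#' One forward-Euler integration step (reference implementation)
#'
#' Coupled Euler update of membrane voltage and synaptic conductance: both
#' derivatives are evaluated at the start of the step, so the voltage
#' update sees the incoming conductance while the conductance
#' simultaneously decays and integrates this step's input spikes.  Neurons
#' reaching threshold spike and reset to rest within the step.  This R
#' implementation defines the single-step semantics; [run_network()] runs
#' the same update in compiled code.
#'
#' @param state an [lif_state()] for the output layer.
#' @param network a [build_network()] object.
#' @param presyn_spikes 0/1 vector of length `n_in`: input spikes this step.
#' @param noise optional vector of length `n_out` of noise currents; if
#'   `NULL`, drawn as `Normal(0, noise_sigma)` (one draw per neuron, in
#'   neuron order, matching the compiled path).
#' @return list with `state` (updated) and `spikes` (0/1 vector, length
#'   `n_out`).
#' @export
lif_step <- function(state, network, presyn_spikes, noise = NULL) {
  p <- network$params
  stopifnot(length(presyn_spikes) == network$n_in,
            length(state$V) == network$n_out)
  if (any(!is.finite(state$V)) || any(!is.finite(state$g)))
    stop("membrane state contains non-finite values")
  drive <- as.numeric(crossprod(network$W, as.numeric(presyn_spikes)))
  if (is.null(noise)) {
    noise <- if (p$noise_sigma > 0) rnorm(network$n_out, 0, p$noise_sigma)
             else rep(0, network$n_out)
  }
  g_old <- state$g
  g_new <- g_old + p$dt * (-g_old / p$tau_syn + p$c_syn * drive)
  V_new <- state$V + (p$dt / p$C) *
    (p$g_L * (p$E_L - state$V) + g_old * (p$E_syn - state$V) + noise)
  spikes <- as.integer(V_new >= p$E_threshold)
  V_new[spikes == 1L] <- p$E_L
  list(state = structure(list(V = V_new, g = g_new), class = "lif_state"),
       spikes = spikes)
}

#' Run the network over a spike raster
#'
#' Iterates the LIF update over all time steps of `input`.  With
#' `plastic = TRUE`, trace-based STDP (all-to-all spike pairing through
#' exponentially decaying pre- and postsynaptic traces) updates the
#' connected weights at every pre- and postsynaptic spike, with clipping to
#' the weight bounds; with `plastic = FALSE` the weights are untouched.
#'
#' @param network a [build_network()] object.
#' @param input a [spike_trains()] raster with `n_neurons == n_in`.
#' @param plastic logical: apply STDP updates?
#' @param seed optional integer seed for the membrane noise; identical
#'   (network, input, seed) triples give identical output.
#' @param force_output optional [spike_trains()] raster over the output
#'   layer: spikes forced onto output neurons at the given times (direct
#'   background drive of the output layer, as in the single-synapse model
#'   where both neurons receive Poisson spikes).  Forced spikes reset the
#'   membrane and take part in STDP exactly like threshold-evoked spikes;
#'   a neuron already spiking at that step is not duplicated.
#' @param state optional carried simulation state (the `state` element of a
#'   previous [run_network()] result): membrane voltages, conductances and
#'   STDP traces, allowing a long session to be run in slices with exact
#'   continuity.  Default: all neurons at rest with empty traces.
#' @return list with `output` (a [spike_trains()] raster over the output
#'   layer), `network` (with final weights) and `state` (final membrane and
#'   trace state, for continuation).
#' @export
run_network <- function(network, input, plastic = FALSE, seed = NULL,
                        force_output = NULL, state = NULL) {
  stopifnot(inherits(network, "feedforward_network"),
            inherits(input, "spike_trains"))
  if (input$n_neurons != network$n_in)
    stop("input raster rows must equal n_in")
  if (is.null(force_output)) {
    f_neuron <- integer(0); f_time <- integer(0)
  } else {
    stopifnot(inherits(force_output, "spike_trains"),
              force_output$n_neurons == network$n_out,
              force_output$n_steps == input$n_steps)
    f_neuron <- force_output$neuron - 1L; f_time <- force_output$time
  }
  res <- with_seed(seed,
    cpp_run_network(network$mask, network$W,
                    input$neuron - 1L, input$time,
                    f_neuron, f_time,
                    input$n_steps, plastic,
                    unclass(network$params), unclass(network$stdp),
                    stdp_alpha(network$stdp), state))
  out <- spike_trains(res$out_neuron + 1L, res$out_step,
                      network$n_out, input$n_steps)
  network$W <- res$W
  list(output = out, network = network, state = res$state)
}
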