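# Independent reference implementations used as oracles.  These deliberately
# avoid the package's incremental trace mechanics: kernel contributions are
# re-summed from scratch over all spike pairs at every event.

# Brute-force all-pairs STDP with a truncation window, mirroring the event
# ordering of the simulator: per step, trace-decayed LTD at presynaptic
# spikes (pairing with all earlier postsynaptic spikes), then postsynaptic
# spikes in ascending neuron order (LTP from all earlier presynaptic spikes,
# then the coincident same-step pair in the LTD branch).
ref_stdp_pairs <- function(network, pre, post, window = Inf) {
  cfg <- network$stdp
  dtt <- network$params$dt
  W <- network$W
  mask <- network$mask
  n_steps <- pre$n_steps
  pre_by_step <- split(pre$neuron, factor(pre$time, levels = 0:(n_steps - 1)))
  post_by_step <- split(post$neuron, factor(post$time, levels = 0:(n_steps - 1)))
  pre_hist <- lapply(seq_len(network$n_in), function(i) numeric(0))
  post_hist <- lapply(seq_len(network$n_out), function(j) numeric(0))
  for (t in 0:(n_steps - 1)) {
    cur_pre <- sort(pre_by_step[[t + 1]])
    cur_post <- sort(post_by_step[[t + 1]])
    for (i in cur_pre) {
      for (j in which(mask[i, ] == 1L)) {
        tp <- post_hist[[j]]
        tp <- tp[t - tp <= window]
        ysum <- sum(exp(-(t - tp) * dtt / cfg$tau_minus))
        w <- W[i, j]
        w <- w + learning_rate(w, "LTD", cfg) * cfg$k_minus * ysum
        W[i, j] <- min(max(w, cfg$w_min), cfg$w_max)
      }
    }
    for (j in cur_post) {
      for (i in which(mask[, j] == 1L)) {
        tq <- pre_hist[[i]]
        tq <- tq[t - tq <= window]
        xsum <- sum(exp(-(t - tq) * dtt / cfg$tau_plus))
        w <- W[i, j]
        w <- w + learning_rate(w, "LTP", cfg) * cfg$k_plus * xsum
        w <- min(max(w, cfg$w_min), cfg$w_max)
        if (i %in% cur_pre) {
          w <- w + learning_rate(w, "LTD", cfg) * cfg$k_minus
          w <- min(max(w, cfg$w_min), cfg$w_max)
        }
        W[i, j] <- w
      }
    }
    for (i in cur_pre) pre_hist[[i]] <- c(pre_hist[[i]], t)
    for (j in cur_post) post_hist[[j]] <- c(post_hist[[j]], t)
  }
  W
}

# naive double-loop memory index, straight from the defining formula
ref_memory_index <- function(S) {
  n <- nrow(S)
  n_firing <- sum(colSums(S) > 0)
  if (n_firing == 0) return(0)
  acc <- 0
  for (m in 1:(n - 1)) {
    for (p in (m + 1):n) acc <- acc + sum(S[m, ] * S[p, ])
  }
  acc / n_firing / (n * (n - 1) / 2)
}

# small random raster with a fixed number of spikes (at most one spike per
# neuron-step cell)
random_raster <- function(n_neurons, n_steps, n_spk) {
  cells <- sample.int(n_neurons * n_steps, n_spk)
  spike_trains(neuron = (cells - 1L) %% n_neurons + 1L,
               time = (cells - 1L) %/% n_neurons,
               n_neurons = n_neurons, n_steps = n_steps)
}

# tiny network helper for plasticity tests
tiny_network <- function(n_in = 6, n_out = 5, profile = "AR", alpha = 0.5,
                         seed = 1, noise_sigma = 1.2) {
  build_network(n_in, n_out, p_connect = 0.6, w_mean = 0.5, w_sd = 0.1,
                params = lif_params(noise_sigma = noise_sigma),
                stdp = stdp_config(profile, alpha = alpha), seed = seed)
}
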