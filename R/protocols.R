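#' Train a network on a temporal pattern
#'
#' Feeds `duration * 1000 / window` back-to-back repetitions of the
#' pattern through a plastic run (STDP on, membrane noise on).  The
#' default protocol of 100 s with a 100-ms pattern gives 1000
#' repetitions.
#'
#' @param network a [build_network()] object.
#' @param pattern an [make_pattern()] object.
#' @param duration training duration, seconds; must be a multiple of the
#'   pattern window.  `duration = 0` returns the network unchanged.
#' @param seed optional integer seed for the training noise.
#' @return the network with updated weights.
#' @export
train <- function(network, pattern, duration, seed = NULL) {
  stopifnot(duration >= 0)
  if (duration == 0) return(network)
  n_reps <- duration * 1000 / pattern$window
  if (abs(n_reps - round(n_reps)) > 1e-9)
    stop("duration must be a whole number of pattern windows")
  raster <- tile_pattern(pattern, round(n_reps))
  run_network(network, raster, plastic = TRUE, seed = seed)$network
}

#' Probe memory of a pattern (read-only test session)
#'
#' Presents `n_trials` repetitions of the pattern with frozen weights
#' (plasticity off, membrane noise on), binarizes the responses per trial
#' and returns the memory index.  The network is never modified by a
#' test.
#'
#' @param network a [build_network()] object.
#' @param pattern an [make_pattern()] object.
#' @param n_trials number of repeated presentations (>= 2).
#' @param seed optional integer seed for the probe noise.
#' @return a [memory_index()] result; the binary [binarize_responses()]
#'   matrix is attached as attribute `"responses"`.
#' @export
test_memory <- function(network, pattern, n_trials = 20, seed = NULL) {
  stopifnot(n_trials >= 2)
  raster <- tile_pattern(pattern, n_trials)
  out <- run_network(network, raster, plastic = FALSE, seed = seed)$output
  resp <- binarize_responses(out, pattern$window, n_trials)
  res <- memory_index(resp)
  attr(res, "responses") <- resp
  res
}

# normalise the `model` argument of the protocol drivers: either an
# stdp_config or a profile name, with `alpha` for "HYBRID"
as_stdp_config <- function(model, alpha = NULL) {
  if (inherits(model, "stdp_config")) return(model)
  if (identical(model, "HYBRID"))
    return(stdp_config("HYBRID", alpha = alpha))
  stdp_config(model)
}

# probe-noise seed tied to the absolute probe time (in whole seconds), so
# changing the probe cadence never re-seeds the probes that remain
probe_seed_at <- function(master, time_s) {
  idx <- as.integer(round(time_s)) + 1L
  derive_seeds(master, idx)[idx]
}

# shared cohort settings for the experiment drivers
default_net_args <- function() {
  list(n_in = 50L, n_out = 50L, p_connect = 0.2, w_mean = 0.5, w_sd = 0.05,
       window = 100L, n_probe_trials = 20L)
}

build_cohort_network <- function(stdp, params, net_args, seed) {
  build_network(net_args$n_in, net_args$n_out, net_args$p_connect,
                net_args$w_mean, net_args$w_sd,
                params = params, stdp = stdp, seed = seed)
}

#' Memory decay under background Poisson noise
#'
#' For each of `n_networks` independently seeded networks: build, train
#' for `train_s` seconds on a freshly drawn pattern, then run `decay_s`
#' seconds of plastic simulation driven by independent `noise_rate`-Hz
#' Poisson spike trains on the input layer (spontaneous background
#' activity that reaches the synapses through the network and erodes the
#' stored weights).  With `noise_on_output = TRUE` the same background
#' rate additionally evokes Poisson spikes directly on the output layer,
#' as in the single-synapse model where both neurons receive Poisson
#' drive; this variant erases memories much more aggressively.  The
#' trained pattern is probed with frozen weights every `probe_every`
#' seconds (including before the decay starts).  Probe noise uses an RNG
#' stream separate from the plastic stream, so probes never perturb the
#' decay trajectory.
#'
#' @param model `"AR"`, `"SR"`, `"HYBRID"` or an [stdp_config()].
#' @param alpha SR proportion when `model = "HYBRID"`.
#' @param train_s training duration, s.
#' @param decay_s decay-session duration, s; a multiple of `probe_every`.
#' @param noise_rate Poisson rate of the background input, Hz.
#' @param probe_every probe cadence, s.
#' @param ratio_at decay time (s) at which the maintained ratio is taken.
#' @param n_networks cohort size.
#' @param seed master seed; spawns one stream per network.
#' @param noise_on_output also drive the output layer with forced
#'   `noise_rate`-Hz Poisson spikes during decay (default `FALSE`:
#'   background activity arrives on the input layer only).
#' @param params an [lif_params()].
#' @param net_args optional overrides of the network/test geometry
#'   (`n_in`, `n_out`, `p_connect`, `w_mean`, `w_sd`, `window`,
#'   `n_probe_trials`).
#' @return an object of class `session_result`: list with `mi_series`
#'   (data.frame: `time_s`, `pattern_id`, `seed`, `mi`, `n_firing`),
#'   `ratios` (data.frame: `seed`, `mi_start`, `mi_end`, `ratio`) and
#'   `settings`.
#' @export
decay_experiment <- function(model = "SR", alpha = NULL, train_s = 100,
                             decay_s = 1000, noise_rate = 5,
                             probe_every = 100, ratio_at = 800,
                             n_networks = 100, seed = 1,
                             noise_on_output = FALSE,
                             params = lif_params(), net_args = list()) {
  stdp <- as_stdp_config(model, alpha)
  net_args <- modifyList(default_net_args(), net_args)
  n_seg <- decay_s / probe_every
  if (abs(n_seg - round(n_seg)) > 1e-9)
    stop("decay_s must be a multiple of probe_every")
  n_seg <- round(n_seg)
  if (ratio_at > decay_s) stop("ratio_at exceeds decay_s")

  net_seeds <- derive_seeds(seed, n_networks)
  series <- vector("list", n_networks)
  ratios <- vector("list", n_networks)
  for (k in seq_len(n_networks)) {
    s <- derive_seeds(net_seeds[k], 5)  # build, pattern, train, decay, probes

    network <- build_cohort_network(stdp, params, net_args, s[1])
    pattern <- make_pattern(net_args$n_in, net_args$window, seed = s[2])
    network <- train(network, pattern, train_s, seed = s[3])

    mi <- numeric(n_seg + 1)
    nf <- integer(n_seg + 1)
    r0 <- test_memory(network, pattern, net_args$n_probe_trials,
                      seed = probe_seed_at(s[5], 0))
    mi[1] <- r0$mi; nf[1] <- r0$n_firing
    # the full decay session is one continuous plastic stream (rasters and
    # membrane noise seeded once, state carried across slices), so the probe
    # cadence has no influence on the weight trajectory
    with_seed(s[4], {
      noise_in <- poisson_train(net_args$n_in, noise_rate, decay_s,
                                dt = params$dt)
      noise_out <- if (noise_on_output)
        poisson_train(net_args$n_out, noise_rate, decay_s, dt = params$dt)
      seg_len <- as.integer(round(probe_every * 1000 / params$dt))
      sim_state <- NULL
      for (seg in seq_len(n_seg)) {
        from <- (seg - 1L) * seg_len
        sl_in <- slice_spike_trains(noise_in, from, seg_len)
        sl_out <- if (noise_on_output)
          slice_spike_trains(noise_out, from, seg_len)
        rr <- run_network(network, sl_in, plastic = TRUE,
                          force_output = sl_out, state = sim_state)
        network <- rr$network
        sim_state <- rr$state
        r <- test_memory(network, pattern, net_args$n_probe_trials,
                         seed = probe_seed_at(s[5], seg * probe_every))
        mi[seg + 1] <- r$mi; nf[seg + 1] <- r$n_firing
      }
    })
    times <- seq(0, decay_s, by = probe_every)
    series[[k]] <- data.frame(time_s = times, pattern_id = "P1",
                              seed = net_seeds[k], mi = mi, n_firing = nf)
    i_end <- which(times == ratio_at)
    ratios[[k]] <- data.frame(seed = net_seeds[k], mi_start = mi[1],
                              mi_end = mi[i_end],
                              ratio = maintained_ratio(mi[1], mi[i_end]))
  }
  structure(list(mi_series = do.call(rbind, series),
                 ratios = do.call(rbind, ratios),
                 settings = list(model = stdp, train_s = train_s,
                                 decay_s = decay_s, noise_rate = noise_rate,
                                 probe_every = probe_every,
                                 ratio_at = ratio_at,
                                 n_networks = n_networks, seed = seed,
                                 noise_on_output = noise_on_output,
                                 net_args = net_args)),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("session_result: %d networks, %d probe rows\n",
              length(unique(x$mi_series$seed)), nrow(x$mi_series)))
  if (!is.null(x$ratios) && nrow(x$ratios))
    cat(sprintf("  maintained ratio: mean %.4f (sd %.4f)\n",
                mean(x$ratios$ratio), sd(x$ratios$ratio)))
  invisible(x)
}

#' Sequential appending of new patterns
#'
#' Trains each network on an ordered sequence of freshly drawn patterns
#' (`P1`, `P2`, ...), `durations[i]` seconds each, probing every
#' `probe_every` seconds.  At each probe point the memory index is
#' measured, with frozen weights, for every pattern whose training has
#' started plus one held-out pattern that is never trained
#' (`pattern_id = "untrained"`).  The convergence ratio of the masked
#' weights is recorded at every probe point.
#'
#' @inheritParams decay_experiment
#' @param n_patterns number of sequentially trained patterns.
#' @param durations vector of training durations (s), one per pattern;
#'   each a multiple of `probe_every`.
#' @param ratio_after if not `NULL`, also report the ratio of MI(P1) at
#'   `durations[1] + ratio_after` seconds to MI(P1) at `durations[1]`
#'   seconds (the appending-session maintained ratio).
#' @return a `session_result`; `mi_series` has one row per (probe time,
#'   probed pattern, network), `convergence` one row per (probe time,
#'   network).
#' @export
append_experiment <- function(model = "SR", alpha = NULL, n_patterns = 7,
                              durations = c(100, rep(200, 6)),
                              probe_every = 100, ratio_after = NULL,
                              n_networks = 100, seed = 1,
                              params = lif_params(), net_args = list()) {
  stdp <- as_stdp_config(model, alpha)
  net_args <- modifyList(default_net_args(), net_args)
  stopifnot(length(durations) == n_patterns, all(durations > 0))
  segs <- durations / probe_every
  if (any(abs(segs - round(segs)) > 1e-9))
    stop("every duration must be a multiple of probe_every")
  segs <- round(segs)
  n_seg_total <- sum(segs)
  pattern_of_seg <- rep(seq_len(n_patterns), segs)

  net_seeds <- derive_seeds(seed, n_networks)
  series <- vector("list", n_networks)
  conv <- vector("list", n_networks)
  ratios <- if (is.null(ratio_after)) NULL else vector("list", n_networks)
  for (k in seq_len(n_networks)) {
    s <- derive_seeds(net_seeds[k], 4)  # build, patterns, train, probes
    pat_seeds <- derive_seeds(s[2], n_patterns + 1)  # + untrained

    network <- build_cohort_network(stdp, params, net_args, s[1])
    patterns <- lapply(pat_seeds[seq_len(n_patterns)], function(ps)
      make_pattern(net_args$n_in, net_args$window, seed = ps))
    untrained <- make_pattern(net_args$n_in, net_args$window,
                              seed = pat_seeds[n_patterns + 1])

    rows <- list(); crows <- list()
    # one continuous plastic training stream across the whole schedule;
    # probes draw from their own streams and never touch it
    with_seed(s[3], {
      sim_state <- NULL
      for (seg in seq_len(n_seg_total)) {
        pid <- pattern_of_seg[seg]
        raster <- tile_pattern(patterns[[pid]],
                               probe_every * 1000 / net_args$window)
        rr <- run_network(network, raster, plastic = TRUE, state = sim_state)
        network <- rr$network
        sim_state <- rr$state
        t_now <- seg * probe_every
        probed <- c(seq_len(pid), 0L)  # trained-so-far plus untrained (id 0)
        psub <- derive_seeds(probe_seed_at(s[4], t_now), length(probed))
        for (q in seq_along(probed)) {
          pat <- if (probed[q] == 0L) untrained else patterns[[probed[q]]]
          lab <- if (probed[q] == 0L) "untrained" else paste0("P", probed[q])
          r <- test_memory(network, pat, net_args$n_probe_trials,
                           seed = psub[q])
          rows[[length(rows) + 1L]] <-
            data.frame(time_s = t_now, pattern_id = lab, seed = net_seeds[k],
                       mi = r$mi, n_firing = r$n_firing)
        }
        crows[[length(crows) + 1L]] <-
          data.frame(time_s = t_now, seed = net_seeds[k],
                     convergence = convergence_ratio(network$W, network$mask,
                                                     eps = 0.1,
                                                     w_min = stdp$w_min,
                                                     w_max = stdp$w_max))
      }
    })
    ser <- do.call(rbind, rows)
    series[[k]] <- ser
    conv[[k]] <- do.call(rbind, crows)
    if (!is.null(ratio_after)) {
      p1 <- ser[ser$pattern_id == "P1", ]
      mi_start <- p1$mi[p1$time_s == durations[1]]
      mi_end <- p1$mi[p1$time_s == durations[1] + ratio_after]
      if (length(mi_start) != 1L || length(mi_end) != 1L)
        stop("ratio_after must align with probe times inside the schedule")
      ratios[[k]] <- data.frame(seed = net_seeds[k], mi_start = mi_start,
                                mi_end = mi_end,
                                ratio = maintained_ratio(mi_start, mi_end))
    }
  }
  structure(list(mi_series = do.call(rbind, series),
                 convergence = do.call(rbind, conv),
                 ratios = if (is.null(ratio_after)) NULL
                          else do.call(rbind, ratios),
                 settings = list(model = stdp, n_patterns = n_patterns,
                                 durations = durations,
                                 probe_every = probe_every,
                                 ratio_after = ratio_after,
                                 n_networks = n_networks, seed = seed,
                                 net_args = net_args)),
            class = "session_result")
}

#' Trained-versus-untrained discrimination cohort
#'
#' Per network: build, train one pattern for `train_s` seconds, then probe
#' both the trained pattern and a held-out untrained pattern with frozen
#' weights.
#'
#' @inheritParams decay_experiment
#' @return data.frame with columns `seed`, `mi_trained`, `mi_untrained`.
#' @export
train_test_experiment <- function(model = "SR", alpha = NULL, train_s = 100,
                                  n_networks = 100, seed = 1,
                                  params = lif_params(), net_args = list()) {
  stdp <- as_stdp_config(model, alpha)
  net_args <- modifyList(default_net_args(), net_args)
  net_seeds <- derive_seeds(seed, n_networks)
  out <- vector("list", n_networks)
  for (k in seq_len(n_networks)) {
    s <- derive_seeds(net_seeds[k], 6)
    network <- build_cohort_network(stdp, params, net_args, s[1])
    trained_pat <- make_pattern(net_args$n_in, net_args$window, seed = s[2])
    untrained_pat <- make_pattern(net_args$n_in, net_args$window, seed = s[3])
    network <- train(network, trained_pat, train_s, seed = s[4])
    r_tr <- test_memory(network, trained_pat, net_args$n_probe_trials,
                        seed = s[5])
    r_un <- test_memory(network, untrained_pat, net_args$n_probe_trials,
                        seed = s[6])
    out[[k]] <- data.frame(seed = net_seeds[k], mi_trained = r_tr$mi,
                           mi_untrained = r_un$mi)
  }
  do.call(rbind, out)
}

#' Sweep the hybrid mixing parameter
#'
#' Runs the decay or appending protocol for each value of `alpha`, reusing
#' the same master seed so that per-network streams are matched across
#' `alpha` values (paired comparisons).  `alpha = 0` and `alpha = 1`
#' reproduce the pure AR and SR rules exactly.
#'
#' @param alphas values of the SR proportion, each in `[0, 1]`.
#' @param experiment `"decay"` or `"append"`.
#' @param n_networks cohort size per `alpha`.
#' @param seed master seed shared across `alpha` values.
#' @param ... further arguments passed to [decay_experiment()] or
#'   [append_experiment()].  For `"append"` the maintained ratio of P1
#'   over the appending session is used (`ratio_after`, default 800 s,
#'   with a default two-pattern schedule `c(100, 900)`).
#' @return list with `summary` (data.frame: `alpha`, `mean_ratio`,
#'   `sd_ratio`), `ratios` (matrix, one column per `alpha`, matched rows
#'   per network seed) and `results` (the per-alpha `session_result`s).
#' @export
hybrid_sweep <- function(alphas, experiment = c("decay", "append"),
                         n_networks = 20, seed = 1, ...) {
  experiment <- match.arg(experiment)
  stopifnot(all(alphas >= 0), all(alphas <= 1))
  results <- vector("list", length(alphas))
  ratio_cols <- vector("list", length(alphas))
  for (i in seq_along(alphas)) {
    res <- if (experiment == "decay") {
      decay_experiment(model = "HYBRID", alpha = alphas[i],
                       n_networks = n_networks, seed = seed, ...)
    } else {
      args <- list(...)
      if (is.null(args$durations)) args$durations <- c(100, 900)
      if (is.null(args$n_patterns)) args$n_patterns <- length(args$durations)
      if (is.null(args$ratio_after)) args$ratio_after <- 800
      do.call(append_experiment,
              c(list(model = "HYBRID", alpha = alphas[i],
                     n_networks = n_networks, seed = seed), args))
    }
    results[[i]] <- res
    ratio_cols[[i]] <- res$ratios$ratio
  }
  ratios <- do.call(cbind, ratio_cols)
  colnames(ratios) <- as.character(alphas)
  list(summary = data.frame(alpha = alphas,
                            mean_ratio = colMeans(ratios),
                            sd_ratio = apply(ratios, 2, sd)),
       ratios = ratios, results = results)
}

#' Output-pattern variability across inputs
#'
#' Clones one fixed initial network (identical mask and weights) and
#' trains the clones (a) on `n_inputs` different patterns and (b)
#' `n_inputs` times on one repeated pattern, each clone with its own noise
#' stream.  The consistently responding set ([output_pattern()]) is
#' extracted per run and all pairwise Pearson correlations are computed
#' within each condition.  Pairs involving a constant pattern (correlation
#' undefined) are dropped.
#'
#' @param n_inputs number of training runs per condition (>= 2).
#' @param train_s training duration per run, s.
#' @param threshold response-fraction threshold for [output_pattern()].
#' @param seed master seed.
#' @inheritParams decay_experiment
#' @return list with `different` and `same`: numeric vectors of pairwise
#'   correlations (up to `choose(n_inputs, 2)` each).
#' @export
output_pattern_study <- function(n_inputs = 100, train_s = 100,
                                 threshold = 0.8, seed = 1,
                                 params = lif_params(), model = "SR",
                                 alpha = NULL, net_args = list()) {
  stopifnot(n_inputs >= 2)
  stdp <- as_stdp_config(model, alpha)
  net_args <- modifyList(default_net_args(), net_args)
  s <- derive_seeds(seed, 4)  # base net, patterns, run seeds (x2 conditions)
  base <- build_cohort_network(stdp, params, net_args, s[1])
  pat_seeds <- derive_seeds(s[2], n_inputs + 1)
  run_one <- function(pattern, run_seed) {
    rs <- derive_seeds(run_seed, 2)
    net <- train(base, pattern, train_s, seed = rs[1])
    r <- test_memory(net, pattern, net_args$n_probe_trials, seed = rs[2])
    output_pattern(attr(r, "responses"), threshold)
  }
  diff_seeds <- derive_seeds(s[3], n_inputs)
  same_seeds <- derive_seeds(s[4], n_inputs)
  shared <- make_pattern(net_args$n_in, net_args$window,
                         seed = pat_seeds[n_inputs + 1])
  pats_diff <- lapply(pat_seeds[seq_len(n_inputs)], function(ps)
    make_pattern(net_args$n_in, net_args$window, seed = ps))
  op_diff <- mapply(run_one, pats_diff, diff_seeds, SIMPLIFY = FALSE)
  op_same <- lapply(same_seeds, function(rs) run_one(shared, rs))
  list(different = pairwise_pattern_cor(op_diff),
       same = pairwise_pattern_cor(op_same))
}

pairwise_pattern_cor <- function(patterns) {
  n <- length(patterns)
  out <- numeric(0)
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      va <- patterns[[a]]; vb <- patterns[[b]]
      if (sd(va) == 0 || sd(vb) == 0) next
      out <- c(out, cor(va, vb))
    }
  }
  out
}
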