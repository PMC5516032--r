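#' Run configuration for the experiment front end
#'
#' A flat key:value configuration (YAML-compatible on disk) that fully
#' specifies an experiment run together with its master seed.  Unknown
#' keys are rejected so a typo cannot silently fall back to a default.
#'
#' @param ... named settings overriding the defaults; see Details.
#' @details Recognised keys: `experiment` (one of `train_test`, `decay`,
#'   `append`, `multi_append`, `hybrid_decay`, `hybrid_append`,
#'   `output_patterns`, `single_synapse`), `model` (`AR`/`SR`/`HYBRID`),
#'   `alpha`, `alphas`, `cohort`, `seed`, `out_dir`, `probe_every`,
#'   `train_s`, `decay_s`, `noise_rate`, `ratio_at`, `n_patterns`,
#'   `durations`, `ratio_after`, `trials`, `duration_s`, `rate_hz`,
#'   `n_inputs`, plus the LIF overrides (`C`, `g_L`, `E_L`, `E_syn`,
#'   `E_threshold`, `tau_syn`, `c_syn`, `noise_sigma`, `dt`) and the STDP
#'   overrides (`k_plus`, `k_minus`, `tau_plus`, `tau_minus`, `w_min`,
#'   `w_max`, `pairing_window`) and network geometry (`n_in`, `n_out`,
#'   `p_connect`, `w_mean`, `w_sd`, `window`).
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(...)
  defaults <- list(experiment = "decay", model = "SR", alpha = 0.5,
                   alphas = c(0, 0.25, 0.5, 0.75, 1), cohort = 100L,
                   seed = 1L, out_dir = "results", probe_every = 100,
                   train_s = 100, decay_s = 1000, noise_rate = 5,
                   ratio_at = 800, n_patterns = 7,
                   durations = c(100, rep(200, 6)), ratio_after = 800,
                   trials = 10000L, duration_s = 1000, rate_hz = 10,
                   n_inputs = 100L)
  lif_keys <- names(formals(lif_params))
  stdp_keys <- setdiff(names(formals(stdp_config)), c("profile", "alpha"))
  net_keys <- c("n_in", "n_out", "p_connect", "w_mean", "w_sd", "window",
                "n_probe_trials")
  known <- c(names(defaults), lif_keys, stdp_keys, net_keys)
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  structure(modifyList(defaults, cfg), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path file path to a flat key:value YAML file.
#' @return `read_run_config` returns a [run_config()];
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# materialise parameter objects from a resolved config
config_params <- function(cfg) {
  lif_args <- cfg[intersect(names(cfg), names(formals(lif_params)))]
  stdp_args <- cfg[intersect(names(cfg),
                             setdiff(names(formals(stdp_config)),
                                     c("profile", "alpha")))]
  net_args <- cfg[intersect(names(cfg),
                            c("n_in", "n_out", "p_connect", "w_mean",
                              "w_sd", "window", "n_probe_trials"))]
  list(params = do.call(lif_params, lif_args),
       stdp = function(profile, alpha = NULL) {
         do.call(stdp_config,
                 c(list(profile = profile),
                   if (identical(profile, "HYBRID")) list(alpha = alpha),
                   stdp_args))
       },
       net_args = net_args)
}

#' Run a named experiment and write its results to disk
#'
#' Dispatches to the protocol drivers, then writes `mi_series.csv`,
#' `summary.json` and the resolved configuration (`config.yaml`) into
#' `config$out_dir`.  A results directory is fully reproducible from its
#' stored config and seed.
#'
#' @param name experiment name: `"train_test"`, `"decay"`, `"append"`
#'   (two patterns), `"multi_append"` (the P1-P7 schedule),
#'   `"hybrid_decay"`, `"hybrid_append"`, `"output_patterns"` or
#'   `"single_synapse"`.
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the experiment result object, invisibly; files under
#'   `config$out_dir`.
#' @export
run_experiment <- function(name, config = run_config(), quiet = FALSE) {
  valid <- c("train_test", "decay", "append", "multi_append",
             "hybrid_decay", "hybrid_append", "output_patterns",
             "single_synapse")
  if (!name %in% valid)
    stop("unknown experiment '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  cp <- config_params(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  say("experiment %s (model %s, cohort %d, seed %d)",
      name, config$model, config$cohort, config$seed)

  model_cfg <- cp$stdp(config$model, config$alpha)
  summary <- list(experiment = name, model = config$model,
                  seed = config$seed, cohort = config$cohort)
  res <- switch(name,
    train_test = {
      d <- train_test_experiment(model = model_cfg,
                                 train_s = config$train_s,
                                 n_networks = config$cohort,
                                 seed = config$seed, params = cp$params,
                                 net_args = cp$net_args)
      write_mi_series(d, file.path(config$out_dir, "mi_series.csv"))
      wt <- wilcox.test(d$mi_trained, d$mi_untrained)
      summary$mean_mi_trained <- mean(d$mi_trained)
      summary$mean_mi_untrained <- mean(d$mi_untrained)
      summary$p_value <- wt$p.value
      d
    },
    decay = {
      r <- decay_experiment(model = model_cfg, train_s = config$train_s,
                            decay_s = config$decay_s,
                            noise_rate = config$noise_rate,
                            probe_every = config$probe_every,
                            ratio_at = config$ratio_at,
                            n_networks = config$cohort, seed = config$seed,
                            params = cp$params, net_args = cp$net_args)
      write_mi_series(r$mi_series, file.path(config$out_dir, "mi_series.csv"))
      summary$mean_ratio <- mean(r$ratios$ratio)
      summary$sd_ratio <- sd(r$ratios$ratio)
      r
    },
    append = ,
    multi_append = {
      durations <- if (name == "append") config$durations[1:2]
                   else config$durations
      r <- append_experiment(model = model_cfg,
                             n_patterns = length(durations),
                             durations = durations,
                             probe_every = config$probe_every,
                             n_networks = config$cohort, seed = config$seed,
                             params = cp$params, net_args = cp$net_args)
      write_mi_series(r$mi_series, file.path(config$out_dir, "mi_series.csv"))
      final_t <- max(r$mi_series$time_s)
      fin <- r$mi_series[r$mi_series$time_s == final_t, ]
      p1 <- fin$mi[fin$pattern_id == "P1"]
      un <- fin$mi[fin$pattern_id == "untrained"]
      wt <- wilcox.test(p1, un)
      summary$final_mi_p1 <- mean(p1)
      summary$final_mi_untrained <- mean(un)
      summary$p_value <- wt$p.value
      r
    },
    hybrid_decay = {
      sw <- hybrid_sweep(config$alphas, "decay",
                         n_networks = config$cohort, seed = config$seed,
                         train_s = config$train_s, decay_s = config$decay_s,
                         noise_rate = config$noise_rate,
                         probe_every = config$probe_every,
                         ratio_at = config$ratio_at, params = cp$params,
                         net_args = cp$net_args)
      write.csv(sw$summary, file.path(config$out_dir, "mi_series.csv"),
                row.names = FALSE)
      summary$alphas <- config$alphas
      summary$mean_ratios <- sw$summary$mean_ratio
      sw
    },
    hybrid_append = {
      sw <- hybrid_sweep(config$alphas, "append",
                         n_networks = config$cohort, seed = config$seed,
                         probe_every = config$probe_every,
                         ratio_after = config$ratio_after,
                         params = cp$params, net_args = cp$net_args)
      write.csv(sw$summary, file.path(config$out_dir, "mi_series.csv"),
                row.names = FALSE)
      summary$alphas <- config$alphas
      summary$mean_ratios <- sw$summary$mean_ratio
      sw
    },
    output_patterns = {
      r <- output_pattern_study(n_inputs = config$n_inputs,
                                train_s = config$train_s,
                                seed = config$seed, params = cp$params,
                                model = model_cfg, net_args = cp$net_args)
      write.csv(data.frame(
        condition = rep(c("different", "same"),
                        c(length(r$different), length(r$same))),
        correlation = c(r$different, r$same)),
        file.path(config$out_dir, "mi_series.csv"), row.names = FALSE)
      wt <- wilcox.test(r$different, r$same)
      summary$mean_cor_different <- mean(r$different)
      summary$mean_cor_same <- mean(r$same)
      summary$p_value <- wt$p.value
      r
    },
    single_synapse = {
      out <- list()
      for (prof in c("AR", "SR")) {
        cfg_p <- cp$stdp(prof)
        w <- simulate_single_synapse(cfg_p, duration = config$duration_s,
                                     rate = config$rate_hz,
                                     n_trials = config$trials,
                                     seed = config$seed)
        write_final_weights(w, file.path(config$out_dir,
                                         paste0("final_weights_",
                                                tolower(prof), ".csv")))
        dens <- boltzmann_density(cfg_p)
        breaks <- seq(cfg_p$w_min, cfg_p$w_max, length.out = 21)
        h <- graphics::hist(w, breaks = breaks, plot = FALSE)
        comp <- data.frame(bin_mid = h$mids, empirical_density = h$density,
                           boltzmann_density =
                             stats::approx(dens$grid, dens$density,
                                           h$mids)$y)
        write.csv(comp, file.path(config$out_dir,
                                  paste0("density_comparison_",
                                         tolower(prof), ".csv")),
                  row.names = FALSE)
        out[[prof]] <- w
        summary[[paste0("mode_bin_", tolower(prof))]] <-
          h$mids[which.max(h$counts)]
      }
      out
    })
  summary$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  say("done in %.1f s; results in %s", summary$elapsed_s, config$out_dir)
  invisible(res)
}
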