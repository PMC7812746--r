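#' Read a pipeline run configuration
#'
#' YAML configuration describing the data source (surrogate generator or
#' network model), the analysis parameters (frequency grid, wavelet
#' cycles, onset, alpha) and the condition comparisons to run. See
#' `system.file("extdata", "demo_config.yaml", package = "ctcoh")` for a
#' complete example.
#'
#' @param path YAML file.
#' @return A `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  ct_assert(file.exists(path), "config file %s does not exist", path)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (same structure as the YAML).
#' @export
as_run_config <- function(cfg) {
  ct_assert(is.list(cfg), "config must be a list")
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$source <- if (is.null(cfg$source)) "surrogate" else cfg$source
  ct_assert(cfg$source %in% c("surrogate", "model"),
            "source must be 'surrogate' or 'model'")
  if (is.null(cfg$analysis)) cfg$analysis <- list()
  a <- cfg$analysis
  if (is.null(a$freqs)) a$freqs <- list(lo = 2, hi = 100, n_points = 30)
  if (is.null(a$cycles)) a$cycles <- 7
  if (is.null(a$alpha)) a$alpha <- 0.05
  if (is.null(a$n_cycles_window)) a$n_cycles_window <- 2
  cfg$analysis <- a
  conds <- names(cfg[[cfg$source]]$conditions)
  ct_assert(length(conds) >= 1, "config must define at least one condition")
  if (is.null(cfg$comparisons)) {
    cfg$comparisons <- list()
  }
  for (cmp in cfg$comparisons) {
    ct_assert(length(cmp) == 2 && all(unlist(cmp) %in% conds),
              "comparison %s references unknown conditions",
              paste(unlist(cmp), collapse = " vs "))
  }
  structure(cfg, class = "run_config")
}

pipeline_log <- function(logfile, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

# Generate the per-condition trial pair (two tf_decomp objects) for the
# surrogate source.
pipeline_surrogate_condition <- function(cfg, cond_name, logfile) {
  sc <- cfg$surrogate
  par <- sc$conditions[[cond_name]]
  spec_args <- sc[setdiff(names(sc), "conditions")]
  spec_args[names(par)] <- par
  spec_args$seed <- child_seed(cfg$seed, match(cond_name, names(sc$conditions)))
  spec <- do.call(surrogate_spec, spec_args)
  out <- gen_coupled_lfp(spec, condition = cond_name)
  pre <- spec$trial_length / 2
  trials <- segment_trials(out$recording, out$events, window = c(pre, pre))
  nch <- spec$n_channels_per_area
  ch_x <- if (!is.null(cfg$analysis$channel_x)) cfg$analysis$channel_x else min(10, nch)
  ch_y <- if (!is.null(cfg$analysis$channel_y)) cfg$analysis$channel_y else nch + min(3, nch)
  list(trials = trials, ch_x = ch_x, ch_y = ch_y, onset = 0)
}

# Same for the network-model source: conditions are stimulation protocols.
pipeline_model_condition <- function(cfg, cond_name, logfile) {
  mc <- cfg$model
  par <- mc$conditions[[cond_name]]
  net_args <- list(seed = child_seed(cfg$seed,
                                     100 + match(cond_name, names(mc$conditions))))
  if (!is.null(mc$s1_m1_superficial_loop)) {
    net_args$s1_m1_superficial_loop <- mc$s1_m1_superficial_loop
  }
  if (!is.null(mc$m1_to_zi)) net_args$m1_to_zi <- mc$m1_to_zi
  net <- do.call(build_network, net_args)
  prot <- stimulus_protocol(
    air_amp = if (is.null(par$air_amp)) 0 else par$air_amp,
    pc_amp = if (is.null(par$pc_amp)) 0 else par$pc_amp,
    delay = if (is.null(par$delay)) 0 else par$delay,
    mode = "steady_state"
  )
  n_trials <- if (is.null(mc$n_trials)) 100 else mc$n_trials
  duration <- if (is.null(mc$duration)) 2 else mc$duration
  trials <- model_trials(net, prot, n_trials = n_trials, duration = duration,
                         seed = net$seed, condition = cond_name)
  onset <- if (is.null(cfg$analysis$onset)) 0.5 else cfg$analysis$onset
  list(trials = trials, ch_x = 1, ch_y = 2, onset = onset)
}

#' Run the full coherence pipeline from a configuration
#'
#' For every condition: generate trials (surrogate or model), decompose the
#' configured channel pair, estimate trial coherence; then run the
#' difference-of-coherence test for every configured comparison. Writes,
#' under `output_dir`: per-comparison DoC tables
#' (`doc_<A>_vs_<B>.tsv`), per-condition coherence spectra
#' (`coherence.tsv`), and `summary.json` with band-averaged coherence and
#' DoC deltas for theta and gamma, the seed and the config hash. The run
#' is deterministic given the seed.
#'
#' @param config A `run_config`, or a path to a YAML config.
#' @param output_dir Output directory (overrides the config entry).
#' @return The summary list, invisibly; side effect: files on disk.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  ct_assert(inherits(config, "run_config"), "config must be a run_config")
  out_dir <- if (!is.null(output_dir)) output_dir else config$output_dir
  ct_assert(!is.null(out_dir), "an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  cat("", file = logfile)
  cfg_hash <- rlang::hash(unclass(config))
  incomplete_flag <- file.path(out_dir, "INCOMPLETE")
  cat("run started\n", file = incomplete_flag)
  a <- config$analysis
  freqs <- default_freq_grid(a$freqs$lo, a$freqs$hi, a$freqs$n_points)
  conds <- names(config[[config$source]]$conditions)
  pipeline_log(logfile, "run config hash %s, seed %d, source %s",
               cfg_hash, config$seed, config$source)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      pipeline_log(logfile, "stage '%s' FAILED: %s", stage,
                   conditionMessage(e))
      ct_stop("pipeline aborted at stage '%s': %s", stage,
              conditionMessage(e))
    })
  }

  coh <- list()
  for (cond in conds) {
    dat <- run_stage(paste0("generate:", cond), {
      if (config$source == "surrogate") {
        pipeline_surrogate_condition(config, cond, logfile)
      } else {
        pipeline_model_condition(config, cond, logfile)
      }
    })
    pipeline_log(logfile,
                 "condition %s: %d trials, channels (%d, %d), onset %g s",
                 cond, dim(dat$trials$data)[1], dat$ch_x, dat$ch_y,
                 dat$onset)
    coh[[cond]] <- run_stage(paste0("coherence:", cond), {
      tf_x <- wavelet_transform(dat$trials, dat$ch_x, freqs, a$cycles)
      tf_y <- wavelet_transform(dat$trials, dat$ch_y, freqs, a$cycles)
      if (isTRUE(a$remove_line_noise)) {
        tf_x <- remove_line_noise(tf_x)
        tf_y <- remove_line_noise(tf_y)
      }
      event_coherence(tf_x, tf_y, onset = dat$onset,
                      n_cycles = a$n_cycles_window)
    })
  }

  coh_tab <- data.frame(f = freqs)
  for (cond in conds) coh_tab[[cond]] <- coh[[cond]]$coherence
  data.table::fwrite(coh_tab, file.path(out_dir, "coherence.tsv"), sep = "\t")

  summary <- list(config_hash = cfg_hash, seed = config$seed,
                  source = config$source, conditions = conds,
                  band_coherence = list(), comparisons = list())
  for (cond in conds) {
    summary$band_coherence[[cond]] <- list(
      theta = band_coherence(coh[[cond]], "theta"),
      gamma = band_coherence(coh[[cond]], "gamma")
    )
  }
  for (cmp in config$comparisons) {
    cmp <- unlist(cmp)
    nm <- sprintf("%s_vs_%s", cmp[1], cmp[2])
    doc <- run_stage(paste0("doc:", nm), {
      doc_test(coh[[cmp[1]]], coh[[cmp[2]]], alpha = a$alpha)
    })
    tab <- doc_table(doc)
    data.table::fwrite(tab, file.path(out_dir, sprintf("doc_%s.tsv", nm)),
                       sep = "\t")
    th <- band_index(freqs, ct_bands()$theta)
    ga <- band_index(freqs, ct_bands()$gamma)
    summary$comparisons[[nm]] <- list(
      delta_theta = mean(doc$delta[th]),
      delta_gamma = mean(doc$delta[ga]),
      n_significant = sum(doc$significant),
      min_p = min(doc$p)
    )
    pipeline_log(logfile, "comparison %s: dC_theta=%.3f dC_gamma=%.3f (%d sig freqs)",
                 nm, mean(doc$delta[th]), mean(doc$delta[ga]),
                 sum(doc$significant))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(incomplete_flag)
  pipeline_log(logfile, "run complete")
  invisible(summary)
}
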