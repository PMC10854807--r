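#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration (defaulting to the packaged
#' `default_config.yaml`, which holds every protocol constant: the
#' 40/60/80 Hz stimulation frequencies, 1 ms pulse width, 2 s duration,
#' 512 Hz analysis rate, 1-200 Hz pass band, 50 Hz mains notch, the 5x
#' channel-rejection ratio, the A-E band edges and the significance
#' levels). User files are merged over the defaults key by key, then
#' validated before any computation runs.
#'
#' @param path optional YAML file; `NULL` uses the packaged defaults.
#' @param overrides optional named list merged over the file (e.g.
#'   `list(seed = 7)`).
#' @return validated configuration list of class `pipeline_config`.
#' @export
load_pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                     package = "lfpturn", mustWork = TRUE))
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- modify_list_deep(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- modify_list_deep(cfg, overrides)
  validate_pipeline_config(cfg)
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(new[[nm]])))
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    else base[[nm]] <- new[[nm]]
  }
  base
}

#' @rdname load_pipeline_config
#' @param cfg a configuration list.
#' @export
validate_pipeline_config <- function(cfg) {
  need <- function(cond, msg) if (!isTRUE(cond)) stop("config: ", msg)
  need(is.numeric(cfg$seed), "seed is mandatory")
  need(is.numeric(cfg$n_subjects) && cfg$n_subjects >= 1,
       "n_subjects must be >= 1")
  need(!is.null(cfg$spectral$bands), "missing bands")
  need(all(BAND_NAMES %in% names(cfg$spectral$bands)),
       "bands must define A..E")
  cfg$spectral$bands <- lapply(cfg$spectral$bands,
                               function(b) as.numeric(unlist(b)))
  for (b in cfg$spectral$bands)
    need(length(b) == 2 && b[1] < b[2], "each band needs edges [lo, hi]")
  need(all(unlist(cfg$stimulation$frequencies_hz) > 0),
       "stimulation frequencies must be positive")
  need(cfg$preprocess$fs_out > 2 * max(vapply(cfg$spectral$bands,
                                              function(b) b[2], 1)),
       "fs_out must exceed twice the highest band edge")
  need(cfg$preprocess$rejection_ratio > 0, "rejection_ratio must be > 0")
  need(cfg$stats$alpha > 0 && cfg$stats$alpha < 1, "alpha must be in (0,1)")
  need(cfg$artifact$threshold_k > 0, "threshold_k must be positive")
  structure(cfg, class = c("pipeline_config", "list"))
}

# synth_config built from the pipeline configuration (per-subject seed)
synth_config_from_pipeline <- function(cfg, seed) {
  s <- cfg$simulate
  synth_config(seed = seed,
               n_trials = unlist(s$n_trials),
               fs_native = s$fs_native,
               pink_exponent = s$pink_exponent,
               pink_rms_uV = s$pink_rms_uV,
               mains_amp_uV = s$mains_amp_uV,
               drift_uV_per_s = s$drift_uV_per_s,
               artifact_spike_ratio = s$artifact_spike_ratio,
               tail_amp_uV = s$tail_amp_uV,
               tail_tau_ms = s$tail_tau_ms,
               turn_duration_mean_s = s$turn_duration_mean_s,
               turn_duration_sd_s = s$turn_duration_sd_s,
               turn_duration_min_s = s$turn_duration_min_s,
               iti_s = s$iti_s,
               epoch_len_s = cfg$spectral$epoch_len_s,
               protocols = list(
                 S40 = stim_protocol(40, cfg$stimulation$pulse_width_ms,
                                     cfg$stimulation$duration_s),
                 S60 = stim_protocol(60, cfg$stimulation$pulse_width_ms,
                                     cfg$stimulation$duration_s),
                 S80 = stim_protocol(80, cfg$stimulation$pulse_width_ms,
                                     cfg$stimulation$duration_s)))
}
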