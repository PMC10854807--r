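#' Configuration for the synthetic session generator
#'
#' Bundles every knob of the synthetic LFP model: per-state per-band
#' oscillation gains, aperiodic (pink) background, 50 Hz mains, slow
#' drift, the stimulation-artifact model (spike-to-resting amplitude
#' ratio, exponential tail), and the behavioural timing model (truncated
#' normal turn durations, inter-trial interval).
#'
#' Band gains are root-mean-square amplitudes (microvolts) of the
#' band-limited oscillatory components in the five avian LFP bands
#' A (0.5-3 Hz), B (4-12 Hz), C (13-60 Hz), D (61-130 Hz), E (131-200 Hz).
#' Defaults follow the qualitative state profile of midbrain recordings:
#' slow/B-band dominance at rest, elevated C/D during active turning, a C
#' boost under 60 Hz stimulation, and elevated D/E (D maximal) under the
#' 80 Hz passive-turning stimulus.
#'
#' @param seed integer seed used by [generate_session()].
#' @param n_trials named integer vector of trials per state
#'   (`AI`, `AT`, `S40`, `S60`, `S80`); states may be omitted.
#' @param fs_native acquisition sampling rate, Hz.
#' @param band_gains 5x5 numeric matrix (rows = states, cols = bands A-E),
#'   microvolt RMS per band component.
#' @param pink_exponent spectral slope of the aperiodic 1/f^a background.
#' @param pink_rms_uV RMS of the aperiodic background, microvolts.
#' @param mains_amp_uV amplitude of the 50 Hz mains component.
#' @param drift_uV_per_s slope of the linear baseline drift.
#' @param artifact_spike_ratio peak instantaneous-artifact amplitude
#'   divided by the channel's resting peak amplitude; must exceed 10.
#' @param tail_amp_uV,tail_tau_ms amplitude and time constant of the
#'   exponentially decaying artifact tail.
#' @param coupling_ipsi,coupling_contra artifact amplitude scaling on
#'   recording channels ipsi-/contralateral to the stimulated site
#'   (the stimulation-site channel couples at 1).
#' @param turn_duration_mean_s,turn_duration_sd_s active-turn duration
#'   model: Normal, truncated below at `turn_duration_min_s`.
#' @param turn_duration_min_s truncation bound, s.
#' @param iti_s inter-trial interval, s. The default is a compressed
#'   desk-scale profile; the behavioural protocol's full 2-minute spacing
#'   is available as `iti_s = 120` (gaps carry no analysed signal).
#' @param stim_noise_uV RMS of instrumentation noise on stim channels.
#' @param protocols named list of [stim_protocol()]s for `S40`, `S60`, `S80`.
#' @param epoch_len_s analysis epoch length, s.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_trials = c(AI = 10, AT = 10, S40 = 10,
                                      S60 = 10, S80 = 10),
                         fs_native = 3000,
                         band_gains = default_band_gains(),
                         pink_exponent = 1,
                         pink_rms_uV = 12,
                         mains_amp_uV = 10,
                         drift_uV_per_s = 2,
                         artifact_spike_ratio = 12,
                         tail_amp_uV = 80,
                         tail_tau_ms = 5,
                         coupling_ipsi = 0.8,
                         coupling_contra = 0.4,
                         turn_duration_mean_s = 1.961,
                         turn_duration_sd_s = 0.201,
                         turn_duration_min_s = 0.5,
                         iti_s = 4,
                         stim_noise_uV = 2,
                         protocols = list(S40 = stim_protocol(40),
                                          S60 = stim_protocol(60),
                                          S80 = stim_protocol(80)),
                         epoch_len_s = 2) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
}

#' @rdname synth_config
#' @param cfg a `synth_config`.
#' @export
validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!all(names(cfg$n_trials) %in% EVENT_STATES))
    stop("n_trials names must be states: ",
         paste(EVENT_STATES, collapse = ", "))
  bg <- cfg$band_gains
  if (!is.matrix(bg) || !all(EVENT_STATES %in% rownames(bg)) ||
      !all(BAND_NAMES %in% colnames(bg)))
    stop("band_gains must be a matrix with state rows and band columns A-E")
  if (any(bg < 0)) stop("band gains must be non-negative")
  if (cfg$artifact_spike_ratio <= 10)
    stop("artifact_spike_ratio must exceed 10 (instantaneous artifact ",
         "spikes are more than 10x the resting amplitude)")
  if (cfg$turn_duration_min_s <= 0)
    stop("turn durations must be truncated above 0")
  if (cfg$fs_native <= 0) stop("fs_native must be positive")
  for (p in cfg$protocols) stopifnot(inherits(p, "stim_protocol"))
  cfg
}

#' @rdname synth_config
#' @export
default_band_gains <- function() {
  rbind(
    AI  = c(A = 3.0, B = 14, C = 3,  D = 1,  E = 0.5),
    AT  = c(A = 2.0, B = 3,  C = 25, D = 35, E = 30),
    S40 = c(A = 3.0, B = 13, C = 3,  D = 1,  E = 0.5),
    S60 = c(A = 2.5, B = 5,  C = 30, D = 8,  E = 2),
    S80 = c(A = 2.0, B = 3,  C = 25, D = 40, E = 35))
}
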