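#' Multichannel LFP recording
#'
#' Container for a continuous multichannel local field potential recording.
#' Samples are stored channel-major as a numeric matrix (rows = samples,
#' columns = channels) in microvolts, together with per-channel metadata:
#' the channel name, the hemisphere it was implanted in, its role in the
#' montage (`record`, `stim`, `reference` or `ground`), and — for recording
#' channels — the name of the nearest-neighbouring stimulated channel used
#' for bipolar re-referencing.
#'
#' @param data numeric matrix, samples x channels, in microvolts. A list of
#'   equal-length numeric vectors is also accepted.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channels data.frame with columns `name`, `hemisphere`
#'   (`"L"`, `"R"` or `"none"`), `role` (`"record"`, `"stim"`,
#'   `"reference"`, `"ground"`) and optionally `paired_stim_channel`.
#' @param start_time offset of the first sample, in seconds.
#'
#' @return An object of class `lfp_recording`.
#' @export
new_recording <- function(data, fs, channels, start_time = 0) {
  if (is.list(data) && !is.matrix(data)) {
    lens <- vapply(data, length, integer(1))
    if (length(unique(lens)) > 1L)
      stop("all channels must have the same number of samples")
    data <- do.call(cbind, lapply(data, as.numeric))
  }
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  if (!"paired_stim_channel" %in% names(channels))
    channels$paired_stim_channel <- NA_character_
  rec <- structure(
    list(data = data, fs = as.numeric(fs), channels = channels,
         start_time = as.numeric(start_time)),
    class = "lfp_recording")
  validate_recording(rec)
}

#' @rdname new_recording
#' @param rec an `lfp_recording`.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  ch <- rec$channels
  req <- c("name", "hemisphere", "role")
  if (!all(req %in% names(ch)))
    stop("channel metadata must have columns: ", paste(req, collapse = ", "))
  if (nrow(ch) == 0L) stop("recording must have at least one channel")
  if (ncol(rec$data) != nrow(ch))
    stop("data has ", ncol(rec$data), " channels but metadata describes ",
         nrow(ch))
  if (anyDuplicated(ch$name)) stop("channel names must be unique")
  if (!all(ch$hemisphere %in% c("L", "R", "none")))
    stop("hemisphere must be one of L, R, none")
  if (!all(ch$role %in% c("record", "stim", "reference", "ground")))
    stop("role must be one of record, stim, reference, ground")
  if (!any(ch$role == "record"))
    stop("recording must contain at least one channel with role 'record'")
  paired <- ch$paired_stim_channel
  known_stim <- ch$name[ch$role == "stim"]
  bad <- !is.na(paired) & !(paired %in% known_stim)
  if (any(bad))
    stop("paired_stim_channel must name an existing stim channel: ",
         paste(unique(paired[bad]), collapse = ", "))
  if (!is.finite(rec$fs) || rec$fs <= 0) stop("fs must be positive")
  if (!all(is.finite(rec$data))) stop("all samples must be finite")
  rec
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  roles <- table(x$channels$role)
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param rec an `lfp_recording`.
#' @return `n_samples`: integer sample count; `duration`: seconds.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' @rdname n_samples
#' @export
rec_duration <- function(rec) nrow(rec$data) / rec$fs

#' Look up a channel's samples by name
#' @param rec an `lfp_recording`.
#' @param name channel name.
#' @return numeric vector of samples in microvolts.
#' @export
channel_data <- function(rec, name) {
  i <- match(name, rec$channels$name)
  if (is.na(i)) stop("no such channel: ", name)
  rec$data[, i]
}

#' Stimulation protocol description
#'
#' Constant-current biphasic (cathodic-leading) pulse train parameters.
#' The pulse count `frequency_hz * duration_s` must be a whole number and
#' the pulse width must fit inside the inter-pulse interval.
#'
#' @param frequency_hz pulse rate, one of 40, 60, 80 in the standard
#'   protocol (other positive rates are accepted for simulation studies).
#' @param pulse_width_ms width of each biphasic pulse, ms.
#' @param duration_s train duration, s.
#' @param amplitude_uA nominal current amplitude (used only by the
#'   synthetic generator to scale the recorded artifact).
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(frequency_hz, pulse_width_ms = 1, duration_s = 2,
                          amplitude_uA = 100) {
  n_pulses <- frequency_hz * duration_s
  if (abs(n_pulses - round(n_pulses)) > 1e-9)
    stop("frequency_hz * duration_s must be an integer pulse count")
  if (pulse_width_ms / 1000 >= 1 / frequency_hz)
    stop("pulse width must be shorter than the inter-pulse interval")
  structure(list(frequency_hz = frequency_hz,
                 pulse_width_ms = pulse_width_ms,
                 duration_s = duration_s,
                 polarity = "biphasic cathodic-leading",
                 amplitude_uA = amplitude_uA),
            class = "stim_protocol")
}
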