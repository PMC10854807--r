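# The conditioning chain applied after artifact suppression:
# resample -> band-pass -> detrend -> mains notch -> stimulation combs ->
# bipolar re-reference -> noisy-channel rejection.

#' Re-reference each recording channel to its nearest stimulated channel
#'
#' Every channel with role `record` gets its paired stimulation-site
#' channel (chosen by implantation location and depth, stored in
#' `paired_stim_channel`) subtracted samplewise. Stim, reference and
#' ground channels pass through unchanged.
#'
#' @param rec an `lfp_recording`; all record channels must have
#'   `paired_stim_channel` set.
#' @return re-referenced `lfp_recording`.
#' @export
rereference_nearest_stim <- function(rec) {
  ch <- rec$channels
  rec_idx <- which(ch$role == "record")
  pair <- ch$paired_stim_channel[rec_idx]
  if (any(is.na(pair)))
    stop("record channel(s) without paired_stim_channel: ",
         paste(ch$name[rec_idx][is.na(pair)], collapse = ", "))
  pj <- match(pair, ch$name)
  if (any(is.na(pj)))
    stop("paired stim channel not found: ",
         paste(pair[is.na(pj)], collapse = ", "))
  out <- rec
  out$data[, rec_idx] <- rec$data[, rec_idx] - rec$data[, pj]
  out
}

#' Reject channels that are noisy during stimulation
#'
#' For each record channel the standard deviation pooled over all
#' during-stimulation windows is divided by the SD pooled over the 2 s
#' pre-stimulation windows; the channel is dropped iff the ratio strictly
#' exceeds `ratio` (a channel at exactly the threshold is retained).
#'
#' @param rec an `lfp_recording`.
#' @param events event table with at least one stimulation trial.
#' @param ratio rejection threshold on the SD ratio.
#' @param epoch_len_s length of the pre-stimulation baseline window, s.
#' @return list: `recording` without the rejected channels, `rejected`
#'   (channel names) and `ratios` (named numeric vector).
#' @export
reject_noisy_channels <- function(rec, events, ratio = 5,
                                  epoch_len_s = 2) {
  events <- validate_events(as.data.frame(events))
  fs <- rec$fs
  stim <- events[events$state %in% STIM_STATES, ]
  if (!nrow(stim)) stop("no stimulation trials in the event table")
  during_idx <- integer(0); pre_idx <- integer(0)
  for (id in unique(stim$trial_id)) {
    tr <- stim[stim$trial_id == id, ]
    on <- tr$time_s[tr$label == "STIM_ON"]
    off <- tr$time_s[tr$label == "STIM_OFF"]
    i_on <- as.integer(floor(on * fs)); i_off <- as.integer(floor(off * fs))
    i_pre <- as.integer(floor((on - epoch_len_s) * fs))
    if (i_pre < 0 || i_off > n_samples(rec)) next
    during_idx <- c(during_idx, (i_on + 1L):i_off)
    pre_idx <- c(pre_idx, (i_pre + 1L):i_on)
  }
  rec_ch <- which(rec$channels$role == "record")
  ratios <- vapply(rec_ch, function(ci)
    stats::sd(rec$data[during_idx, ci]) / stats::sd(rec$data[pre_idx, ci]),
    numeric(1))
  names(ratios) <- rec$channels$name[rec_ch]
  drop <- ratios > ratio                 # strict: ratio == threshold kept
  if (all(drop))
    stop("all record channels rejected; analysis cannot proceed")
  out <- rec
  keep <- setdiff(seq_len(ncol(rec$data)), rec_ch[drop])
  out$data <- rec$data[, keep, drop = FALSE]
  out$channels <- rec$channels[keep, ]
  rownames(out$channels) <- NULL
  list(recording = out, rejected = names(ratios)[drop], ratios = ratios)
}

#' Run the full preprocessing chain on a recording
#'
#' Applies, in order: downsampling to 512 Hz, 1-200 Hz zero-phase
#' band-pass, linear detrending, 50 Hz mains notch, comb filters at every
#' stimulation frequency present in the events, bipolar re-referencing to
#' the nearest stimulated channel, and (when stimulation trials exist)
#' noisy-channel rejection. Artifact suppression
#' ([reject_artifacts()]) is expected to have run first, at the native
#' rate: the sub-millisecond artifact spikes cannot be represented at
#' 512 Hz.
#'
#' @param rec an `lfp_recording` (artifact-cleaned).
#' @param events the session's event table.
#' @param fs_out target rate, Hz.
#' @param rejection_ratio SD-ratio threshold for channel rejection
#'   (`NULL` disables the step).
#' @param rereference apply bipolar re-referencing (default TRUE).
#' @param comb apply stimulation-frequency comb filters (default TRUE).
#' @return list: `recording` (preprocessed, at `fs_out`), `rejected`
#'   channel names, `ratios`, and `steps` (character log of the chain).
#' @export
preprocess_recording <- function(rec, events, fs_out = 512,
                                 rejection_ratio = 5, rereference = TRUE,
                                 comb = TRUE) {
  events <- validate_events(as.data.frame(events))
  steps <- character(0)
  data <- apply(rec$data, 2, resample_512, fs_in = rec$fs, fs_out = fs_out)
  rec <- new_recording(data, fs_out, rec$channels, rec$start_time)
  steps <- c(steps, sprintf("resample_%g", fs_out))
  rec$data <- apply(rec$data, 2, bandpass_1_200, fs = fs_out)
  steps <- c(steps, "bandpass_1_200")
  rec$data <- apply(rec$data, 2, detrend_linear)
  steps <- c(steps, "detrend_linear")
  rec$data <- apply(rec$data, 2, notch_50, fs = fs_out)
  steps <- c(steps, "notch_50")
  stim_states <- intersect(unique(events$state), STIM_STATES)
  if (comb && length(stim_states)) {
    freqs <- c(S40 = 40, S60 = 60, S80 = 80)[stim_states]
    for (f in freqs) {
      rec$data <- apply(rec$data, 2, comb_stim, fs = fs_out, stim_freq = f)
      steps <- c(steps, sprintf("comb_%g", f))
    }
  }
  if (rereference) {
    rec <- rereference_nearest_stim(rec)
    steps <- c(steps, "rereference_nearest_stim")
  }
  rejected <- character(0); ratios <- numeric(0)
  if (!is.null(rejection_ratio) && length(stim_states)) {
    rj <- reject_noisy_channels(rec, events, ratio = rejection_ratio)
    rec <- rj$recording; rejected <- rj$rejected; ratios <- rj$ratios
    steps <- c(steps, "reject_noisy_channels")
  }
  list(recording = rec, rejected = rejected, ratios = ratios, steps = steps)
}
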