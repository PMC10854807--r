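# Stimulation-artifact suppression: threshold detection of instantaneous
# artifact spikes, per-frequency tail templates, template subtraction,
# and excision of the 1.4 ms spike window with flank in-fill.

SPIKE_PRE_MS  <- 0.6   # excision window extends 0.6 ms before ...
SPIKE_POST_MS <- 0.8   # ... and 0.8 ms after the artifact time

#' Detect instantaneous stimulation-artifact spikes by thresholding
#'
#' Samples whose absolute value exceeds `threshold_k` robust standard
#' deviations of the pre-stimulation baseline (robust SD = 1.4826 x the
#' median absolute deviation) are clustered: crossings within 2 ms of a
#' cluster's first crossing belong to that cluster. The reported artifact
#' time of a cluster is the midpoint of its first and last crossing,
#' which centres the 1.4 ms excision window (0.6 ms before to 0.8 ms
#' after) on the biphasic spike. Each detection defines one excision
#' interval; overlapping intervals are merged.
#'
#' @param signal numeric vector (the stimulation segment), microvolts.
#' @param fs sampling rate, Hz.
#' @param baseline pre-stimulation baseline samples (>= 0.5 s).
#' @param threshold_k detection threshold in robust baseline SDs.
#' @param duration_s denominator of the excised fraction (defaults to the
#'   segment length).
#' @return object of class `spike_detection` with `spike_times_s`
#'   (seconds from segment start), `intervals` (two-column matrix of
#'   merged excision windows, s), `excised_fraction`, `sigma` and
#'   `threshold`.
#' @export
detect_spikes <- function(signal, fs, baseline, threshold_k = 8,
                          duration_s = length(signal) / fs) {
  if (length(baseline) == 0L) stop("baseline segment is empty")
  if (length(baseline) < 0.5 * fs)
    stop("baseline segment must cover at least 0.5 s")
  sigma <- stats::mad(baseline)
  thr <- threshold_k * sigma
  idx <- which(abs(signal) > thr)
  times <- numeric(0)
  if (length(idx)) {
    t_cross <- (idx - 1) / fs
    gap <- 2e-3
    start <- t_cross[1]; last <- t_cross[1]
    for (tc in t_cross[-1]) {
      if (tc - start < gap) last <- tc
      else {
        times <- c(times, (start + last) / 2)
        start <- tc; last <- tc
      }
    }
    times <- c(times, (start + last) / 2)
  }
  iv <- cbind(times - SPIKE_PRE_MS / 1000, times + SPIKE_POST_MS / 1000)
  iv <- merge_intervals(iv)
  structure(list(spike_times_s = times, intervals = iv,
                 excised_fraction =
                   if (nrow(iv)) sum(iv[, 2] - iv[, 1]) / duration_s else 0,
                 sigma = sigma, threshold = thr, fs = fs),
            class = "spike_detection")
}

merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else out <- rbind(out, iv[i, ])
  }
  out
}

#' @export
print.spike_detection <- function(x, ...) {
  cat(sprintf("<spike_detection> %d spikes, excised fraction %.3f\n",
              length(x$spike_times_s), x$excised_fraction))
  invisible(x)
}

# default tail window: up to 20 ms, but never past the next pulse
default_tail_window_ms <- function(stim_freq) {
  min(20, 1000 / stim_freq - (SPIKE_PRE_MS + SPIKE_POST_MS))
}

#' Build the per-frequency artifact-tail template
#'
#' Extracts the tail window `[t + 0.8 ms, t + 0.8 ms + tail_window_ms)`
#' after every detected spike time `t` and averages the tails pointwise.
#' Tails of the same stimulation frequency share one template.
#'
#' @param signal segment the detections refer to.
#' @param det a [detect_spikes()] result (times may also come from pooled
#'   detections across trials; pass them via `times_s`).
#' @param stim_freq stimulation frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param tail_window_ms tail length, ms; default
#'   `min(20, 1000/stim_freq - 1.4)`.
#' @param min_tails minimum number of tails required for a stable average.
#' @param times_s optional explicit spike times overriding `det`.
#' @return object of class `artifact_template`: `waveform` (microvolts),
#'   `stim_frequency_hz`, `n_tails`, `offset_samples` (samples between a
#'   spike time and the first tail sample), `fs`.
#' @export
build_tail_templates <- function(signal, det, stim_freq, fs,
                                 tail_window_ms = NULL, min_tails = 10,
                                 times_s = NULL) {
  if (is.null(times_s)) times_s <- det$spike_times_s
  if (length(times_s) == 0L) stop("no detections to build a template from")
  if (is.null(tail_window_ms)) tail_window_ms <- default_tail_window_ms(stim_freq)
  off <- as.integer(round(SPIKE_POST_MS / 1000 * fs))
  len <- as.integer(round(tail_window_ms / 1000 * fs))
  if (len < 1L) stop("tail window shorter than one sample")
  tails <- list()
  for (t in times_s) {
    i0 <- as.integer(floor(t * fs + 0.5)) + 1L + off
    if (i0 + len - 1L <= length(signal) && i0 >= 1L)
      tails[[length(tails) + 1L]] <- signal[i0:(i0 + len - 1L)]
  }
  if (length(tails) < min_tails)
    stop("only ", length(tails), " artifact tails available (need >= ",
         min_tails, "); record a longer stimulation session")
  wf <- rowMeans(do.call(cbind, tails))
  structure(list(stim_frequency_hz = stim_freq, waveform = wf,
                 n_tails = length(tails), offset_samples = off, fs = fs),
            class = "artifact_template")
}

#' Subtract the tail template at every detected spike
#'
#' The template is subtracted in the tail window after each spike time;
#' samples outside tail windows are untouched. A window running past the
#' end of the signal is subtracted truncated, with a warning.
#'
#' @param signal numeric vector.
#' @param det a [detect_spikes()] result (or `times_s` override).
#' @param template an [build_tail_templates()] result at the same `fs`.
#' @param times_s optional explicit spike times.
#' @return the signal with tails removed.
#' @export
subtract_tails <- function(signal, det, template, times_s = NULL) {
  if (is.null(times_s)) times_s <- det$spike_times_s
  fs <- template$fs
  wf <- template$waveform
  len <- length(wf)
  for (t in times_s) {
    i0 <- as.integer(floor(t * fs + 0.5)) + 1L + template$offset_samples
    if (i0 > length(signal) || i0 < 1L) next
    i1 <- i0 + len - 1L
    if (i1 > length(signal)) {
      warning("tail window truncated at end of signal")
      i1 <- length(signal)
    }
    signal[i0:i1] <- signal[i0:i1] - wf[seq_len(i1 - i0 + 1L)]
  }
  signal
}

#' Excise spike windows and fill them from flanking raw signal
#'
#' Each detected spike's 1.4 ms window (0.6 ms before to 0.8 ms after the
#' artifact time) is treated as missing. The missing left part
#' `[t-0.6, t)` is filled with a verbatim copy of `[t-1.2, t-0.6)` and the
#' right part `[t, t+0.8)` with a copy of `[t+0.8, t+1.6)`. If a flank
#' overlaps a neighbouring excision window, the nearest clean segment of
#' equal length is used instead (reported via a message). No crossfade is
#' applied; all other samples are bit-identical.
#'
#' @param signal numeric vector.
#' @param det a [detect_spikes()] result.
#' @param fs sampling rate, Hz.
#' @param times_s optional explicit spike times.
#' @return the signal with spike windows replaced.
#' @export
excise_and_fill <- function(signal, det, fs, times_s = NULL) {
  if (is.null(times_s)) times_s <- det$spike_times_s
  if (!length(times_s)) return(signal)
  o_pre <- as.integer(round(SPIKE_PRE_MS / 1000 * fs))
  o_post <- as.integer(round(SPIKE_POST_MS / 1000 * fs))
  centers <- as.integer(floor(times_s * fs + 0.5)) + 1L
  excised <- cbind(centers - o_pre, centers + o_post - 1L)  # index ranges
  overlaps_excision <- function(a, b)
    any(a <= excised[, 2] & b >= excised[, 1])
  clean_source <- function(pref_a, len, direction) {
    a <- pref_a
    while (overlaps_excision(a, a + len - 1L))
      a <- a + direction * len
    a
  }
  out <- signal
  n <- length(signal)
  for (c0 in centers) {
    la <- c0 - o_pre; lb <- c0 - 1L              # left missing part
    ra <- c0; rb <- c0 + o_post - 1L             # right missing part
    if (la < 1L || rb > n) {
      warning("excision window at signal boundary skipped")
      next
    }
    src_l <- c0 - 2L * o_pre
    if (overlaps_excision(src_l, src_l + o_pre - 1L)) {
      src_l <- clean_source(src_l, o_pre, -1L)
      message("left flank overlapped a neighbouring excision; ",
              "used nearest clean segment")
    }
    src_r <- c0 + o_post
    if (overlaps_excision(src_r, src_r + o_post - 1L)) {
      src_r <- clean_source(src_r, o_post, +1L)
      message("right flank overlapped a neighbouring excision; ",
              "used nearest clean segment")
    }
    if (src_l >= 1L && o_pre > 0L)
      out[la:lb] <- signal[src_l:(src_l + o_pre - 1L)]
    if (src_r + o_post - 1L <= n && o_post > 0L)
      out[ra:rb] <- signal[src_r:(src_r + o_post - 1L)]
  }
  out
}

#' Suppress stimulation artifacts across a whole recording
#'
#' For every stimulation trial, each stimulation-site channel is
#' thresholded within `[STIM_ON - pad_s, STIM_OFF + pad_s]` against its
#' own 2 s pre-stimulation baseline. Detection times are shared with the
#' recording channels paired to that stimulation channel; every channel
#' of the pair then gets its own per-frequency tail template (pooled over
#' all trials of that frequency), tail subtraction, and spike excision
#' with flank fill. Samples outside stimulation windows are untouched.
#'
#' @param rec an `lfp_recording`.
#' @param events an event table containing the stimulation trials.
#' @param threshold_k detection threshold in robust baseline SDs.
#' @param tail_window_ms tail-template length cap, ms.
#' @param min_tails minimum pooled tails per (channel, frequency).
#' @param pad_s padding around the stimulation interval, s.
#' @param subtract_tail set `FALSE` to skip template subtraction and only
#'   excise the spike windows.
#' @return list: `recording` (cleaned), `report` (data.frame with one row
#'   per trial x channel: detections, excised fraction) and `templates`
#'   (per channel x frequency diagnostics).
#' @export
reject_artifacts <- function(rec, events, threshold_k = 8,
                             tail_window_ms = 20, min_tails = 10,
                             pad_s = 0.05, subtract_tail = TRUE) {
  events <- validate_events(as.data.frame(events))
  fs <- rec$fs
  ch <- rec$channels
  stim_trials <- unique(events$trial_id[events$state %in% STIM_STATES])
  if (!length(stim_trials))
    return(list(recording = rec,
                report = data.frame(), templates = list()))

  trial_info <- lapply(stim_trials, function(id) {
    tr <- events[events$trial_id == id, ]
    list(id = id, state = tr$state[1],
         on = tr$time_s[tr$label == "STIM_ON"],
         off = tr$time_s[tr$label == "STIM_OFF"])
  })
  state_freq <- c(S40 = 40, S60 = 60, S80 = 80)

  # stimulated site per trial: the stim channel with the largest artifact
  # amplitude during the train (tail shape depends on which site was
  # driven, so templates are grouped by frequency x stimulated site)
  stim_ch_idx <- which(ch$role == "stim")
  trial_site <- vapply(trial_info, function(ti) {
    i0 <- as.integer(floor(ti$on * fs)) + 1L
    i1 <- min(nrow(rec$data), as.integer(floor(ti$off * fs)))
    peaks <- vapply(stim_ch_idx, function(ci)
      max(abs(rec$data[i0:i1, ci])), numeric(1))
    ch$name[stim_ch_idx[which.max(peaks)]]
  }, character(1))
  names(trial_site) <- vapply(trial_info, function(ti)
    as.character(ti$id), character(1))

  data <- rec$data
  report <- list(); templates <- list()
  for (s_name in ch$name[ch$role == "stim"]) {
    si <- match(s_name, ch$name)
    pair_idx <- unique(c(si, which(ch$paired_stim_channel == s_name)))

    # pass 1: detect per trial on the stim-site channel
    dets <- list()
    for (ti in trial_info) {
      w0 <- max(0, ti$on - pad_s); w1 <- ti$off + pad_s
      i0 <- as.integer(floor(w0 * fs)) + 1L
      i1 <- min(nrow(data), as.integer(floor(w1 * fs)))
      b0 <- max(1L, as.integer(floor((ti$on - 2) * fs)) + 1L)
      b1 <- as.integer(floor(ti$on * fs))
      det <- detect_spikes(data[i0:i1, si], fs, data[b0:b1, si],
                           threshold_k = threshold_k,
                           duration_s = ti$off - ti$on)
      dets[[as.character(ti$id)]] <-
        list(det = det, i0 = i0, i1 = i1, info = ti,
             freq = state_freq[[ti$state]],
             site = trial_site[[as.character(ti$id)]])
    }

    # pass 2: per channel of the pair, templates pooled per frequency and
    # stimulated site
    groups <- unique(vapply(dets, function(d)
      paste(d$freq, d$site), character(1)))
    for (ci in pair_idx) {
      for (grp in groups) {
        these <- Filter(function(d) paste(d$freq, d$site) == grp, dets)
        f <- these[[1]]$freq
        if (!any(vapply(these, function(d)
          length(d$det$spike_times_s) > 0, logical(1)))) next
        twin <- min(tail_window_ms, default_tail_window_ms(f))
        # pool tails across trials by averaging per-trial sums
        off <- as.integer(round(SPIKE_POST_MS / 1000 * fs))
        len <- as.integer(round(twin / 1000 * fs))
        acc <- numeric(len); n_tails <- 0L
        for (d in these) {
          seg <- data[d$i0:d$i1, ci]
          for (t in d$det$spike_times_s) {
            j0 <- as.integer(floor(t * fs + 0.5)) + 1L + off
            if (j0 >= 1L && j0 + len - 1L <= length(seg)) {
              acc <- acc + seg[j0:(j0 + len - 1L)]
              n_tails <- n_tails + 1L
            }
          }
        }
        if (n_tails < min_tails)
          stop("only ", n_tails, " artifact tails for channel ",
               ch$name[ci], " at ", f,
               " Hz (need >= ", min_tails, "); record a longer session")
        tmpl <- structure(list(stim_frequency_hz = f,
                               waveform = acc / n_tails,
                               n_tails = n_tails,
                               offset_samples = off, fs = fs),
                          class = "artifact_template")
        templates[[paste0(ch$name[ci], "_", f, "Hz_",
                          these[[1]]$site)]] <- tmpl
        for (d in these) {
          seg <- data[d$i0:d$i1, ci]
          if (subtract_tail)
            seg <- subtract_tails(seg, d$det, tmpl)
          seg <- excise_and_fill(seg, d$det, fs)
          data[d$i0:d$i1, ci] <- seg
          report[[length(report) + 1L]] <- data.frame(
            trial_id = d$info$id, state = d$info$state,
            channel = ch$name[ci], stim_channel = s_name,
            n_detections = length(d$det$spike_times_s),
            excised_fraction = d$det$excised_fraction)
        }
      }
    }
  }
  out <- rec
  out$data <- data
  list(recording = out,
       report = if (length(report)) do.call(rbind, report) else data.frame(),
       templates = templates)
}
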