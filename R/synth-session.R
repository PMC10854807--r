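#' Generate a full synthetic recording session
#'
#' Builds a continuous 4-channel session (left/right recording channels
#' `L1`/`R1` paired with left/right stimulation-site channels `LS`/`RS`),
#' an event table, and a ground-truth object for validation. Trials of the
#' requested states are shuffled and scheduled sequentially; each trial
#' block spans a 2 s pre window, the behavioural/stimulation interval, and
#' a 2 s post window, separated by inter-trial gaps of resting (`AI`)
#' background. Active-turn durations are drawn from a truncated normal
#' distribution; stimulation trials superpose a biphasic artifact train
#' (spike amplitude = `artifact_spike_ratio` x the channel's resting peak,
#' scaled by ipsi/contra coupling) on the state background.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `recording` (an `lfp_recording`), `events`
#'   (an `lfp_events` table) and `ground_truth` (list: `clean` background
#'   matrix without artifacts, `pulse_times` per stimulation trial,
#'   `trials` schedule data.frame, `stim_channel` per trial,
#'   `band_gains` as configured).
#' @export
generate_session <- function(cfg) {
  validate_synth_config(cfg)
  set.seed(cfg$seed)
  fs <- cfg$fs_native
  ep <- cfg$epoch_len_s

  states <- rep(names(cfg$n_trials), times = cfg$n_trials)
  states <- sample(states)
  n_tr <- length(states)
  if (n_tr == 0L) stop("n_trials is empty")

  # --- schedule ------------------------------------------------------
  cursor <- 1
  sched <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    cursor <- ceiling(cursor * fs) / fs   # sample-align block starts
    st <- states[i]
    anchor <- cursor + ep
    if (st == "AT") {
      dur <- repeat_trunc_norm(cfg$turn_duration_mean_s,
                               cfg$turn_duration_sd_s,
                               cfg$turn_duration_min_s)
      t_end <- anchor + dur
    } else {
      dur <- ep
      t_end <- anchor + ep
    }
    block_end <- t_end + ep
    sched[[i]] <- data.frame(trial_id = i, state = st,
                             block_start = cursor, anchor = anchor,
                             t_end = t_end, block_end = block_end,
                             duration = dur)
    cursor <- block_end + cfg$iti_s
  }
  sched <- do.call(rbind, sched)
  total_s <- cursor
  n <- as.integer(ceiling(total_s * fs))

  channels <- data.frame(
    name = c("L1", "R1", "LS", "RS"),
    hemisphere = c("L", "R", "L", "R"),
    role = c("record", "record", "stim", "stim"),
    paired_stim_channel = c("LS", "RS", NA, NA),
    stringsAsFactors = FALSE)
  rec_idx <- which(channels$role == "record")
  stim_idx <- which(channels$role == "stim")
  data <- matrix(0, n, nrow(channels))

  # --- background ----------------------------------------------------
  seg_bounds <- sort(unique(c(0, sched$block_start, sched$block_end,
                              total_s)))
  for (k in seq_len(length(seg_bounds) - 1L)) {
    s0 <- seg_bounds[k]; s1 <- seg_bounds[k + 1L]
    i0 <- as.integer(floor(s0 * fs)); i1 <- as.integer(floor(s1 * fs))
    if (i1 > n) i1 <- n
    len <- i1 - i0
    if (len <= 0L) next
    inside <- which(sched$block_start <= s0 + 1e-9 &
                      sched$block_end >= s1 - 1e-9)
    st <- if (length(inside)) sched$state[inside[1]] else "AI"
    for (ci in rec_idx)
      data[(i0 + 1L):i1, ci] <- generate_background(st, len / fs, cfg)
    for (ci in stim_idx)   # stim-site electrodes record LFP too
      data[(i0 + 1L):i1, ci] <- generate_background(st, len / fs, cfg) +
        stats::rnorm(len, sd = cfg$stim_noise_uV)
  }
  clean <- data

  # --- artifacts on stimulation trials -------------------------------
  stim_rows <- which(sched$state %in% STIM_STATES)
  pulse_times <- vector("list", n_tr)
  stim_channel <- rep(NA_character_, n_tr)
  for (i in stim_rows) {
    st <- sched$state[i]
    proto <- cfg$protocols[[st]]
    hemi <- sample(c("L", "R"), 1)
    stim_channel[i] <- channels$name[channels$role == "stim" &
                                       channels$hemisphere == hemi]
    on_t <- sched$anchor[i]
    i_on <- as.integer(floor(on_t * fs))
    pre_idx <- (as.integer(floor((on_t - ep) * fs)) + 1L):i_on
    for (ci in seq_len(nrow(channels))) {
      coupling <-
        if (channels$name[ci] == stim_channel[i]) 1
        else if (channels$role[ci] == "stim") cfg$coupling_contra
        else if (channels$hemisphere[ci] == hemi) cfg$coupling_ipsi
        else cfg$coupling_contra
      resting_peak <- max(abs(data[pre_idx, ci]))
      amp <- cfg$artifact_spike_ratio * resting_peak * coupling
      train <- generate_artifact_train(proto, cfg, fs, amp,
                                       tail_amp_uV = cfg$tail_amp_uV *
                                         coupling)
      idx <- (i_on + 1L):(i_on + length(train$signal))
      data[idx, ci] <- data[idx, ci] + train$signal
      if (channels$name[ci] == stim_channel[i])
        pulse_times[[i]] <- on_t + train$pulse_times
    }
  }

  # --- events --------------------------------------------------------
  ev <- lapply(seq_len(n_tr), function(i) {
    r <- sched[i, ]
    switch(r$state,
      AT = data.frame(time_s = c(r$anchor, r$t_end), label = c("TB", "TE"),
                      trial_id = i, state = r$state),
      AI = data.frame(time_s = r$anchor, label = "TRIAL_START",
                      trial_id = i, state = r$state),
      data.frame(time_s = c(r$anchor, r$t_end),
                 label = c("STIM_ON", "STIM_OFF"),
                 trial_id = i, state = r$state))
  })
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  events <- validate_events(ev)

  rec <- new_recording(data, fs, channels)
  list(recording = rec,
       events = events,
       ground_truth = list(clean = clean,
                           pulse_times = pulse_times,
                           trials = sched,
                           stim_channel = stim_channel,
                           band_gains = cfg$band_gains))
}

# truncated-normal draw by rejection
repeat_trunc_norm <- function(mean, sd, lower) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
}
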