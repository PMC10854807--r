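#' Extract pre / during / post epochs around behavioural events
#'
#' For each trial three fixed-length windows are cut from the recording,
#' using half-open intervals `[start, end)` and 0-based sample indices
#' (`index = floor(t * fs)`):
#' * active turning (`AT`): pre = `[TB-2, TB)`, during = `[TB, TB+2)`,
#'   post = `[TE, TE+2)`;
#' * stimulation trials (`S40`/`S60`/`S80`): as above with
#'   TB := `STIM_ON`, TE := `STIM_OFF`;
#' * awake immobile (`AI`): during = `[TRIAL_START, TRIAL_START+2)` with
#'   pre and post windows adjacent on either side.
#'
#' The during window has fixed length `epoch_len_s` regardless of the
#' actual turn duration; trials whose windows fall outside the recording
#' are skipped with a warning.
#'
#' @param rec an `lfp_recording`.
#' @param events a validated event table.
#' @param epoch_len_s epoch length in seconds (default 2).
#' @return list of `lfp_epoch` objects, each holding `state`, `phase`
#'   (`pre`/`during`/`post`), `trial_id`, `fs`, `t0` (absolute window start,
#'   s) and `data` (samples x channels matrix).
#' @export
extract_epochs <- function(rec, events, epoch_len_s = 2.0) {
  events <- validate_events(as.data.frame(events))
  fs <- rec$fs
  n <- n_samples(rec)
  len <- as.integer(round(epoch_len_s * fs))
  out <- list()
  for (id in unique(events$trial_id)) {
    tr <- events[events$trial_id == id, ]
    st <- tr$state[1]
    anchors <- switch(
      st,
      AT = {
        tb <- tr$time_s[tr$label == "TB"]; te <- tr$time_s[tr$label == "TE"]
        c(pre = tb - epoch_len_s, during = tb, post = te)
      },
      AI = {
        t0 <- tr$time_s[tr$label == "TRIAL_START"]
        c(pre = t0 - epoch_len_s, during = t0, post = t0 + epoch_len_s)
      },
      {
        on <- tr$time_s[tr$label == "STIM_ON"]
        off <- tr$time_s[tr$label == "STIM_OFF"]
        c(pre = on - epoch_len_s, during = on, post = off)
      })
    starts <- floor(anchors * fs)            # 0-based
    if (any(starts < 0) || any(starts + len > n)) {
      warning(sprintf("trial %d (%s): epoch window outside recording; skipped",
                      id, st))
      next
    }
    for (ph in names(anchors)) {
      i0 <- starts[[ph]]
      out[[length(out) + 1L]] <- structure(
        list(state = st, phase = ph, trial_id = id, fs = fs,
             t0 = anchors[[ph]],
             data = rec$data[(i0 + 1L):(i0 + len), , drop = FALSE]),
        class = "lfp_epoch")
    }
  }
  out
}

#' @export
print.lfp_epoch <- function(x, ...) {
  cat(sprintf("<lfp_epoch> trial %d %s/%s, %d samples @ %g Hz from t=%.3f s\n",
              x$trial_id, x$state, x$phase, nrow(x$data), x$fs, x$t0))
  invisible(x)
}

#' Filter an epoch list by state and/or phase
#' @param epochs list of `lfp_epoch`.
#' @param state,phase optional values to keep.
#' @return filtered list.
#' @export
filter_epochs <- function(epochs, state = NULL, phase = NULL) {
  keep <- vapply(epochs, function(e) {
    (is.null(state) || e$state %in% state) &&
      (is.null(phase) || e$phase %in% phase)
  }, logical(1))
  epochs[keep]
}
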