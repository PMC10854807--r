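#' Behavioural / stimulation event tables
#'
#' Events are stored as a data.frame with columns `time_s` (seconds from
#' recording start), `label` (one of `TB`, `TE`, `STIM_ON`, `STIM_OFF`,
#' `TRIAL_START`), `trial_id` (integer) and `state` (one of `AI`, `AT`,
#' `S40`, `S60`, `S80`). `TB`/`TE` bracket an active turn; `STIM_ON`/
#' `STIM_OFF` bracket a stimulation train; `TRIAL_START` anchors an
#' awake-immobile trial.
#'
#' @name event_table
NULL

EVENT_LABELS <- c("TB", "TE", "STIM_ON", "STIM_OFF", "TRIAL_START")
EVENT_STATES <- c("AI", "AT", "S40", "S60", "S80")
STIM_STATES  <- c("S40", "S60", "S80")

#' Construct and validate an event table
#'
#' @param time_s event times in seconds (non-negative).
#' @param label event labels; see [event_table].
#' @param trial_id integer trial identifiers.
#' @param state behavioural state codes.
#' @param stim_duration_s if given, every stimulation trial is checked to
#'   have `STIM_OFF - STIM_ON` equal to this duration (within `tol_s`).
#' @param tol_s tolerance in seconds for the duration check.
#' @return A validated `data.frame` of class `lfp_events`.
#' @export
new_events <- function(time_s, label, trial_id, state,
                       stim_duration_s = NULL, tol_s = 1e-6) {
  ev <- data.frame(time_s = as.numeric(time_s),
                   label = as.character(label),
                   trial_id = as.integer(trial_id),
                   state = as.character(state),
                   stringsAsFactors = FALSE)
  validate_events(ev, stim_duration_s = stim_duration_s, tol_s = tol_s)
}

#' @rdname new_events
#' @param events a data.frame with the event-table columns.
#' @export
validate_events <- function(events, stim_duration_s = NULL, tol_s = 1e-6) {
  req <- c("time_s", "label", "trial_id", "state")
  if (!all(req %in% names(events)))
    stop("event table must have columns: ", paste(req, collapse = ", "))
  if (any(!events$label %in% EVENT_LABELS))
    stop("unknown event label(s): ",
         paste(unique(setdiff(events$label, EVENT_LABELS)), collapse = ", "))
  if (any(!events$state %in% EVENT_STATES))
    stop("unknown state token(s): ",
         paste(unique(setdiff(events$state, EVENT_STATES)), collapse = ", "))
  if (any(events$time_s < 0)) stop("event times must be non-negative")
  for (id in unique(events$trial_id)) {
    tr <- events[events$trial_id == id, ]
    if (is.unsorted(tr$time_s))
      stop("event times out of order within trial ", id)
    if (length(unique(tr$state)) > 1L)
      stop("trial ", id, " has inconsistent state codes")
    st <- tr$state[1]
    if (st == "AT") {
      tb <- tr$time_s[tr$label == "TB"]; te <- tr$time_s[tr$label == "TE"]
      if (length(tb) != 1L || length(te) != 1L)
        stop("AT trial ", id, " must have exactly one TB and one TE event")
      if (!(tb < te)) stop("trial ", id, ": TE must follow TB")
    }
    if (st %in% STIM_STATES) {
      on <- tr$time_s[tr$label == "STIM_ON"]
      off <- tr$time_s[tr$label == "STIM_OFF"]
      if (length(on) != 1L || length(off) != 1L)
        stop("stim trial ", id, " must have exactly one STIM_ON and STIM_OFF")
      if (!is.null(stim_duration_s) &&
          abs((off - on) - stim_duration_s) > tol_s)
        stop("trial ", id, ": STIM_OFF - STIM_ON != stimulation duration")
      if (off <= on) stop("trial ", id, ": STIM_OFF must follow STIM_ON")
    }
  }
  class(events) <- c("lfp_events", "data.frame")
  events
}

#' Read / write an event table as tab-separated text
#'
#' The on-disk format is TSV with a mandatory header line
#' `time_s<TAB>label<TAB>trial_id<TAB>state`; lines starting with `#` are
#' comments. Validation (label/state vocabularies, within-trial time order,
#' TB < TE) is enforced on read.
#'
#' @param path file path.
#' @return `read_events` returns a validated `lfp_events` data.frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ev <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c("numeric", "character",
                                         "integer", "character"))
  validate_events(ev)
}

#' @rdname read_events
#' @param events an event table.
#' @export
write_events <- function(events, path) {
  events <- validate_events(as.data.frame(events))
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
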