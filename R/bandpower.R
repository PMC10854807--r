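#' Build the subject x hemisphere x state x band power table
#'
#' For each subject session: channels with role `record` are grouped by
#' hemisphere; for every state, the Welch PSD of each `during` epoch is
#' reduced to the five band means, those linear band powers are averaged
#' across the cell's epochs and channels, and `log10` is applied to the
#' cell mean. One row per subject x hemisphere x state x band. Cells with
#' no epochs are emitted with `log_power = NA` and flagged, so a
#' downstream repeated-measures ANOVA can refuse the incomplete design by
#' name.
#'
#' @param sessions list of per-subject sessions, each a list with
#'   elements `subject` (identifier), `recording` (preprocessed
#'   `lfp_recording`) and `events`.
#' @param bands band definitions (default [band_specs()]).
#' @param phase which epoch phase enters the statistics (default
#'   `"during"`).
#' @param epoch_len_s epoch length, s.
#' @return data.frame of class `band_power_table` with columns `subject`,
#'   `hemisphere`, `state`, `band`, `log_power`, `n_epochs`.
#' @export
build_band_power_table <- function(sessions, bands = band_specs(),
                                   phase = "during", epoch_len_s = 2) {
  rows <- list()
  for (ses in sessions) {
    rec <- ses$recording
    epochs <- extract_epochs(rec, ses$events, epoch_len_s = epoch_len_s)
    epochs <- filter_epochs(epochs, phase = phase)
    ch <- rec$channels
    for (hemi in c("L", "R")) {
      ci <- which(ch$role == "record" & ch$hemisphere == hemi)
      for (st in EVENT_STATES) {
        eps <- filter_epochs(epochs, state = st)
        cell <- matrix(NA_real_, 0, nrow(bands))
        if (length(ci) && length(eps)) {
          for (e in eps) for (c1 in ci) {
            psd <- welch_psd(e$data[, c1], fs = rec$fs)
            cell <- rbind(cell, band_power(psd, bands, log = FALSE))
          }
        }
        lp <- if (nrow(cell)) log10(colMeans(cell)) else
          rep(NA_real_, nrow(bands))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = ses$subject, hemisphere = hemi, state = st,
          band = bands$name, log_power = lp, n_epochs = nrow(cell),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("band_power_table", "data.frame")
  out
}

#' Read / write a band-power table as TSV
#' @param path file path.
#' @return `read_band_power_table` returns a `band_power_table`.
#' @export
read_band_power_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  class(x) <- c("band_power_table", "data.frame")
  x
}

#' @rdname read_band_power_table
#' @param table a `band_power_table`.
#' @export
write_band_power_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
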