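# Minimal EDF (European Data Format) reader/writer for equal-rate
# multichannel recordings. 16-bit samples; one data record per second.
# Channel roles and exact sample counts do not fit EDF's 16-char labels,
# so they travel in a JSON sidecar `<name>.channels.json`.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF field too long: ", s)
  formatC(s, width = -width)  # left-justified, blank padded
}

# format a number into <= `width` ascii chars, losslessly re-parseable
edf_num_field <- function(x, width = 8) {
  for (digits in seq(10, 1)) {
    s <- formatC(x, digits = digits, format = "g", width = 0)
    if (nchar(s) <= width) return(s)
  }
  stop("cannot format ", x, " in ", width, " chars")
}

sidecar_path <- function(path) {
  sub("\\.edf$", "", path, ignore.case = TRUE) |> paste0(".channels.json")
}

#' Write a recording to disk as EDF plus a JSON metadata sidecar
#'
#' Samples are quantized to 16 bits over each channel's symmetric physical
#' range; the final partial data record is zero-padded and the true sample
#' count is recorded in the sidecar so the round trip preserves length.
#'
#' @param rec an [new_recording()] object.
#' @param path output path (conventionally `*.edf`). The sidecar is written
#'   next to it as `<name>.channels.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  rec <- validate_recording(rec)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- ncol(rec$data)
  n <- nrow(rec$data)
  n_rec <- max(1L, as.integer(ceiling(n / fs)))

  pmaxs <- pmax(apply(abs(rec$data), 2, max), 1e-6)
  pmax_str <- vapply(pmaxs, edf_num_field, character(1))
  pmin_str <- vapply(-pmaxs, edf_num_field, character(1))
  pmaxs <- as.numeric(pmax_str)   # use the on-disk precision for scaling
  pmins <- as.numeric(pmin_str)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),
    edf_field("Startdate 01-JAN-2000 synthetic", 80),
    edf_field("01.01.00", 8),
    edf_field("00.00.00", 8),
    edf_field(256 * (1 + nch), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field("1", 8),
    edf_field(nch, 4),
    paste(vapply(rec$channels$name, edf_field, character(1), width = 16),
          collapse = ""),
    paste(rep(edf_field("", 80), nch), collapse = ""),
    paste(rep(edf_field("uV", 8), nch), collapse = ""),
    paste(vapply(pmin_str, edf_field, character(1), width = 8), collapse = ""),
    paste(vapply(pmax_str, edf_field, character(1), width = 8), collapse = ""),
    paste(rep(edf_field(dmin, 8), nch), collapse = ""),
    paste(rep(edf_field(dmax, 8), nch), collapse = ""),
    paste(rep(edf_field("", 80), nch), collapse = ""),
    paste(rep(edf_field(fs, 8), nch), collapse = ""),
    paste(rep(edf_field("", 32), nch), collapse = ""))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  scale <- (dmax - dmin) / (pmaxs - pmins)
  dig <- sweep(rec$data, 2, pmins)
  dig <- round(sweep(dig, 2, scale, `*`) + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  padded <- matrix(0L, nrow = n_rec * fs, ncol = nch)
  padded[seq_len(n), ] <- as.integer(dig)
  # record-major layout: record r holds fs samples of ch1, then ch2, ...
  arr <- array(padded, dim = c(fs, n_rec, nch))
  out <- as.integer(aperm(arr, c(1, 3, 2)))
  writeBin(out, con, size = 2, endian = "little")

  meta <- list(fs = fs, n_samples = n, start_time = rec$start_time,
               channels = rec$channels)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

read_edf_header <- function(con) {
  take <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    if (length(raw) == 0L || nchar(raw, type = "bytes") < w)
      stop("malformed EDF: truncated header")
    trimws(raw)
  }
  version <- take(8)
  if (version != "0") stop("malformed EDF: bad version field '", version, "'")
  take(80); take(80); take(8); take(8)
  header_bytes <- as.integer(take(8))
  take(44)
  n_rec <- as.integer(take(8))
  rec_dur <- as.numeric(take(8))
  nch <- as.integer(take(4))
  if (is.na(nch) || nch < 1L) stop("malformed EDF: bad signal count")
  fld <- function(w) vapply(seq_len(nch), function(i) take(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmins <- as.numeric(fld(8)); pmaxs <- as.numeric(fld(8))
  dmins <- as.numeric(fld(8)); dmaxs <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (header_bytes != 256 * (1 + nch))
    stop("malformed EDF: header size mismatch")
  list(n_rec = n_rec, rec_dur = rec_dur, nch = nch, labels = labels,
       pmins = pmins, pmaxs = pmaxs, dmins = dmins, dmaxs = dmaxs, spr = spr)
}

#' Read an EDF recording and its channel-metadata sidecar
#'
#' @param path path to an EDF file written by [write_recording()] (any
#'   equal-rate EDF is accepted; without a sidecar, channels default to
#'   role `record`, hemisphere `none`).
#' @return an `lfp_recording` in microvolts.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$spr)) > 1L)
    stop("unsupported EDF: channels have mixed sampling rates")
  fs <- h$spr[1] / h$rec_dur
  total <- h$n_rec * h$spr[1] * h$nch
  raw <- readBin(con, "integer", n = total, size = 2, endian = "little")
  if (length(raw) < total) stop("malformed EDF: truncated data section")
  arr <- array(as.numeric(raw), dim = c(h$spr[1], h$nch, h$n_rec))
  dig <- matrix(aperm(arr, c(1, 3, 2)), ncol = h$nch)
  phys <- sweep(sweep(dig, 2, h$dmins),
                2, (h$pmaxs - h$pmins) / (h$dmaxs - h$dmins), `*`)
  phys <- sweep(phys, 2, h$pmins, `+`)

  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    channels <- as.data.frame(meta$channels, stringsAsFactors = FALSE)
    if (!is.null(meta$n_samples)) phys <- phys[seq_len(meta$n_samples), ,
                                               drop = FALSE]
    start_time <- if (is.null(meta$start_time)) 0 else meta$start_time
  } else {
    warning("no channel sidecar found for ", path,
            "; defaulting all channels to role 'record'")
    channels <- data.frame(name = h$labels, hemisphere = "none",
                           role = "record",
                           paired_stim_channel = NA_character_,
                           stringsAsFactors = FALSE)
    start_time <- 0
  }
  new_recording(phys, fs, channels, start_time = start_time)
}

#' Quantization step of the 16-bit EDF encoding for each channel
#' @param rec an `lfp_recording`.
#' @return numeric vector, microvolts per digital unit.
#' @export
edf_quantization_step <- function(rec) {
  pmaxs <- pmax(apply(abs(rec$data), 2, max), 1e-6)
  pmaxs <- as.numeric(vapply(pmaxs, edf_num_field, character(1)))
  2 * pmaxs / 65535
}
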