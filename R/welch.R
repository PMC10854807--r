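#' Welch power spectral density estimate
#'
#' Averages modified periodograms of Hamming-windowed segments of
#' `seg_len` samples (default `fs`, giving a 1.0 Hz frequency grid) with
#' 50% overlap, using density scaling so that the PSD integrates to the
#' signal's variance (one-sided, microvolts squared per Hz).
#'
#' @param signal numeric vector, at least `seg_len` samples (>= 1 s).
#' @param fs sampling rate, Hz.
#' @param seg_len segment length in samples (sets the resolution
#'   `fs / seg_len` Hz).
#' @param overlap fractional segment overlap.
#' @return object of class `psd_estimate`: data.frame-like list with
#'   `freqs` (Hz, `0 .. fs/2`) and `power` (µV²/Hz).
#' @export
welch_psd <- function(signal, fs = 512, seg_len = fs, overlap = 0.5) {
  n <- length(signal)
  seg_len <- as.integer(seg_len)
  if (n < seg_len)
    stop("signal too short for Welch PSD: need at least ", seg_len,
         " samples")
  w <- hamming_window(seg_len)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  scale <- 1 / (fs * sum(w^2))
  for (s in starts) {
    X <- stats::fft(signal[s:(s + seg_len - 1L)] * w)[seq_len(nf)]
    acc <- acc + Mod(X)^2 * scale
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when seg_len even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (seg_len %% 2L == 0L) dbl[nf] <- 1
  structure(list(freqs = (seq_len(nf) - 1L) * fs / seg_len,
                 power = p * dbl, fs = fs, n_segments = length(starts)),
            class = "psd_estimate")
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, %g-%g Hz (df = %g Hz), %d segments\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_segments))
  invisible(x)
}

#' The five avian LFP frequency bands
#'
#' Band edges (Hz, inclusive): A 0.5-3, B 4-12, C 13-60, D 61-130,
#' E 131-200. The bands do not tile the axis: 1 Hz bins centred in the
#' gaps (e.g. at 3.5 or 60.5 Hz) belong to no band.
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
band_specs <- function() {
  data.frame(name = BAND_NAMES,
             lo = c(0.5, 4, 13, 61, 131),
             hi = c(3, 12, 60, 130, 200),
             stringsAsFactors = FALSE)
}

BAND_NAMES <- c("A", "B", "C", "D", "E")

#' Mean absolute band power from a PSD
#'
#' The band's absolute power is the arithmetic mean of the PSD bins with
#' `lo <= f <= hi` (inclusive edges). With `log = TRUE` the decadic log of
#' that mean is returned. When powers are first averaged across an epoch
#' set, apply the log to the cell mean (see [build_band_power_table()]).
#'
#' @param psd a [welch_psd()] result (must cover 0.5-200 Hz).
#' @param bands band definition data.frame (default [band_specs()]).
#' @param log return `log10` of the band means.
#' @return named numeric vector, one value per band.
#' @export
band_power <- function(psd, bands = band_specs(), log = TRUE) {
  if (max(psd$freqs) < max(bands$hi))
    stop("PSD does not cover the requested bands")
  out <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- psd$freqs >= bands$lo[i] & psd$freqs <= bands$hi[i]
    if (!any(sel)) stop("band ", bands$name[i], " contains no PSD bins")
    mean(psd$power[sel])
  }, numeric(1))
  names(out) <- bands$name
  if (log) log10(out) else out
}
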