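# Filtering primitives: polyphase rational resampling and the zero-phase
# IIR filters of the conditioning chain.

.filter_cache <- new.env(parent = emptyenv())

# Kaiser-windowed low-pass FIR for rational resampling by p/q, designed at
# the upsampled rate. Each polyphase branch is normalised to unit sum so a
# constant input is reproduced exactly.
resample_fir <- function(p, q, fs_in, f_pass, f_stop, atten_db = 70) {
  key <- paste(p, q, fs_in, f_pass, f_stop, sep = "_")
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  fs_up <- fs_in * p
  dw <- 2 * pi * (f_stop - f_pass) / fs_up
  L <- ceiling((atten_db - 8) / (2.285 * dw))
  if (L %% 2 == 0) L <- L + 1            # odd length -> integer group delay
  beta <- 0.1102 * (atten_db - 8.7)
  wc <- (f_pass + f_stop) / fs_up        # normalised to Nyquist = 1
  h <- signal::fir1(L - 1, wc, type = "low",
                    window = signal::kaiser(L, beta))
  phase <- (seq_along(h) - 1) %% p
  sums <- tapply(h, phase, sum)
  h <- h / as.numeric(sums[as.character(phase)])
  out <- list(h = h, L = L, D = (L - 1) / 2)
  .filter_cache[[key]] <- out
  out
}

#' Downsample a signal to 512 Hz
#'
#' Polyphase rational resampling by `512/fs_in` with a Kaiser-windowed FIR
#' anti-aliasing filter (passband to 205 Hz, stopband from the lowest
#' frequency that aliases below 205 Hz, 70 dB attenuation). The filter is
#' linear-phase and the output is aligned to the input grid, so the
#' operation is zero-phase. Output length is `round(n * 512 / fs_in)`.
#'
#' @param signal numeric vector.
#' @param fs_in input sampling rate, Hz (must be >= 512).
#' @param fs_out output rate, Hz.
#' @return numeric vector at `fs_out` Hz.
#' @export
resample_512 <- function(signal, fs_in, fs_out = 512) {
  if (fs_in < fs_out) stop("fs_in must be at least ", fs_out, " Hz")
  n <- length(signal)
  if (fs_in == fs_out) return(signal)
  g <- gcd_int(round(fs_out), round(fs_in))
  p <- round(fs_out) / g; q <- round(fs_in) / g
  f_pass <- 205
  f_stop <- fs_out - f_pass
  fir <- resample_fir(p, q, fs_in, f_pass, f_stop)
  h <- fir$h; L <- fir$L; D <- fir$D
  K <- ceiling(L / p) + 1L
  n_out <- as.integer(round(n * p / q))
  xpad <- c(rep(signal[1], K), signal, rep(signal[n], K + 1L))
  m <- seq_len(n_out) - 1L
  u <- m * q + D                          # upsampled-grid index of output m
  j_hi <- u %/% p                         # highest contributing input index
  y <- numeric(n_out)
  for (r in 0:(K - 1L)) {
    j <- j_hi - r
    k <- u - j * p                        # 0-based tap index
    ok <- k >= 0L & k < L
    if (!any(ok)) next
    y[ok] <- y[ok] + h[k[ok] + 1L] * xpad[j[ok] + 1L + K]
  }
  y
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Zero-phase 1-200 Hz Butterworth band-pass
#'
#' Butterworth band-pass (order 4 per edge) applied forward and backward
#' with [signal::filtfilt()], giving zero phase and doubled attenuation.
#'
#' @param signal numeric vector.
#' @param fs sampling rate, Hz (must exceed 400 so the 200 Hz edge is
#'   below Nyquist).
#' @param lo,hi band edges, Hz.
#' @param order Butterworth design order per edge.
#' @return filtered signal.
#' @export
bandpass_1_200 <- function(signal, fs, lo = 1, hi = 200, order = 4) {
  if (hi >= fs / 2) stop("fs too low for the ", hi, " Hz band edge")
  flt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(flt, signal)
}

#' Remove the least-squares linear trend
#'
#' Subtracts the ordinary least-squares fit of `a + b t`, leaving a
#' residual orthogonal to both the constant and the ramp regressor.
#'
#' @param signal numeric vector.
#' @return detrended signal.
#' @export
detrend_linear <- function(signal) {
  n <- length(signal)
  if (n < 2) return(signal - mean(signal))
  t <- seq_len(n) - (n + 1) / 2           # centred ramp, orthogonal to 1
  signal - mean(signal) - sum(signal * t) / sum(t * t) * t
}

# RBJ biquad notch at f0 with quality Q, returned as an Arma filter
iir_notch <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b / a[1], a / a[1])
}

#' Zero-phase 50 Hz mains notch
#'
#' Second-order IIR notch (quality factor `Q`) applied forward-backward.
#'
#' @param signal numeric vector.
#' @param fs sampling rate, Hz.
#' @param f0 notch centre, Hz.
#' @param Q quality factor (centre / -3 dB bandwidth).
#' @return filtered signal.
#' @export
notch_50 <- function(signal, fs, f0 = 50, Q = 30) {
  if (f0 >= fs / 2) stop("notch centre above Nyquist")
  signal::filtfilt(iir_notch(f0, fs, Q), signal)
}

#' Comb filter at the stimulation frequency and its harmonics
#'
#' Cascaded zero-phase IIR notches at `stim_freq`, `2*stim_freq`, ... for
#' every harmonic below `max_hz` (e.g. 80 and 160 Hz for the 80 Hz
#' protocol), suppressing residual stimulation artifacts.
#'
#' @param signal numeric vector.
#' @param fs sampling rate, Hz.
#' @param stim_freq stimulation frequency, Hz.
#' @param Q per-notch quality factor.
#' @param max_hz highest harmonic to notch (exclusive).
#' @return filtered signal.
#' @export
comb_stim <- function(signal, fs, stim_freq, Q = 30, max_hz = 200) {
  harmonics <- seq(stim_freq, max_hz - 1e-9, by = stim_freq)
  for (f0 in harmonics) signal <- notch_50(signal, fs, f0 = f0, Q = Q)
  signal
}
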