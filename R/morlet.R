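#' Morlet wavelet time-frequency map
#'
#' Convolves the signal with complex Morlet wavelets (centre parameter
#' `omega0`, so a wavelet at frequency `f` has temporal SD
#' `omega0 / (2 pi f)` seconds) and returns squared-magnitude power for
#' each frequency and sample. Convolution is done in the frequency domain
#' with the analytic (positive-frequency Gaussian) Morlet kernel. Samples
#' closer to either edge than one wavelet half-width (3 temporal SDs) are
#' flagged as edge-contaminated.
#'
#' @param signal numeric vector (one epoch).
#' @param fs sampling rate, Hz.
#' @param freqs analysis frequencies, Hz (default 1-200 in 1 Hz steps);
#'   all must lie below Nyquist.
#' @param omega0 nondimensional Morlet centre frequency (cycles
#'   parameter).
#' @return object of class `tfa_map`: `freqs`, `times` (s), `power`
#'   (matrix `length(freqs)` x `n_times`, µV² units up to the wavelet
#'   normalisation) and `edge` (logical matrix flagging edge samples).
#' @export
morlet_tfa <- function(signal, fs, freqs = 1:200, omega0 = 6) {
  if (any(freqs >= fs / 2))
    stop("analysis frequencies must be below Nyquist (", fs / 2, " Hz)")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  n <- length(signal)
  npad <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(signal, numeric(npad - n)))
  w <- 2 * pi * fft_freqs(npad, fs)      # angular frequency per FFT bin
  power <- matrix(0, length(freqs), n)
  edge <- matrix(FALSE, length(freqs), n)
  t_axis <- (seq_len(n) - 1) / fs
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    s <- omega0 / (2 * pi * f)           # temporal SD, seconds
    H <- exp(-0.5 * (s * w - omega0)^2)
    H[w < 0] <- 0
    W <- stats::fft(X * H, inverse = TRUE)[seq_len(n)] / npad
    power[i, ] <- Mod(W)^2
    hw <- 3 * s
    edge[i, ] <- t_axis < hw | t_axis > (n - 1) / fs - hw
  }
  structure(list(freqs = freqs, times = t_axis, power = power,
                 edge = edge, omega0 = omega0, fs = fs),
            class = "tfa_map")
}

#' @export
print.tfa_map <- function(x, ...) {
  cat(sprintf("<tfa_map> %d freqs x %d times (%g-%g Hz, %.2f s)\n",
              nrow(x$power), ncol(x$power), min(x$freqs), max(x$freqs),
              max(x$times)))
  invisible(x)
}
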