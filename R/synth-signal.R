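# Signal-level synthesis primitives. All generators draw from R's global
# RNG; seed via set.seed() (generate_session() seeds from cfg$seed).

#' Band-limited Gaussian noise with exact RMS
#'
#' White Gaussian noise is masked in the FFT domain to the closed band
#' `[lo, hi]` Hz and rescaled so its sample RMS equals `rms` exactly
#' (zero-RMS degenerate draws return zeros).
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param lo,hi band edges, Hz.
#' @param rms target root-mean-square amplitude.
#' @return numeric vector of length `n`.
#' @export
band_limited_noise <- function(n, fs, lo, hi, rms) {
  if (rms == 0 || n < 2) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))     # smooth FFT length, then truncate
  x <- stats::rnorm(m)
  f <- fft_freqs(m, fs)
  X <- stats::fft(x)
  X[!(abs(f) >= lo & abs(f) <= hi)] <- 0
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  r <- sqrt(mean(y^2))
  if (r == 0) return(numeric(n))
  y * (rms / r)
}

#' 1/f^a (pink) background noise
#'
#' FFT-shaped Gaussian noise with amplitude spectrum proportional to
#' `f^(-a/2)`, band-limited to the acquisition band `[f_lo, f_hi]` and
#' rescaled to the target RMS.
#'
#' @param n,fs samples and rate.
#' @param exponent spectral exponent `a` of the 1/f^a power spectrum.
#' @param rms target RMS.
#' @param f_lo,f_hi acquisition band edges, Hz (hardware analog filter).
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, exponent = 1, rms = 1,
                       f_lo = 0.05, f_hi = 500) {
  if (rms == 0 || n < 2) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  f <- fft_freqs(m, fs)
  shape <- ifelse(abs(f) >= f_lo & abs(f) <= min(f_hi, fs / 2),
                  abs(f)^(-exponent / 2), 0)
  X <- stats::fft(stats::rnorm(m)) * shape
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  y * (rms / sqrt(mean(y^2)))
}

fft_freqs <- function(n, fs) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k * fs / n
}

#' Synthesise state-dependent background LFP
#'
#' The background is a sum of five band-limited Gaussian components (one
#' per band A-E, scaled to the state's configured RMS gains), pink noise,
#' a 50 Hz mains sinusoid with random phase, and a linear drift ramp.
#'
#' @param state one of `AI`, `AT`, `S40`, `S60`, `S80`.
#' @param duration_s length of the segment, s (> 0).
#' @param cfg a [synth_config()].
#' @param return_components if TRUE, attach the per-band component matrix
#'   as attribute `"components"` (columns A-E) for recovery testing.
#' @return numeric vector of `round(duration_s * fs)` samples, microvolts.
#' @export
generate_background <- function(state, duration_s, cfg,
                                return_components = FALSE) {
  if (!state %in% EVENT_STATES) stop("unknown state: ", state)
  stopifnot(duration_s > 0)
  fs <- cfg$fs_native
  n <- as.integer(round(duration_s * fs))
  bands <- band_specs()
  gains <- cfg$band_gains[state, ]
  comp <- matrix(0, n, nrow(bands), dimnames = list(NULL, bands$name))
  for (i in seq_len(nrow(bands)))
    comp[, i] <- band_limited_noise(n, fs, bands$lo[i], bands$hi[i],
                                    gains[[bands$name[i]]])
  t <- (seq_len(n) - 1) / fs
  y <- rowSums(comp) +
    pink_noise(n, fs, cfg$pink_exponent, cfg$pink_rms_uV) +
    cfg$mains_amp_uV * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi)) +
    cfg$drift_uV_per_s * t
  if (return_components) attr(y, "components") <- comp
  y
}

#' Synthesise a biphasic stimulation-artifact train
#'
#' One cathodic-leading biphasic spike per pulse (negative then positive
#' phase, each half the pulse width), with peak amplitude
#' `amplitude_uV`, followed by a deterministic exponentially decaying
#' tail `tail_amp * exp(-t / tau)` that is identical across pulses in
#' continuous time. Returns the waveform and the ground-truth pulse
#' onset times for detector validation.
#'
#' @param protocol a [stim_protocol()].
#' @param cfg a [synth_config()] (tail parameters).
#' @param fs sampling rate, Hz (must resolve the pulse width).
#' @param amplitude_uV spike peak amplitude on this channel, microvolts.
#' @param tail_amp_uV tail starting amplitude (defaults to the configured
#'   value scaled by `amplitude_uV / (spike amplitude at coupling 1)`).
#' @return list with `signal` (length `duration_s * fs` samples) and
#'   `pulse_times` (s, relative to train onset).
#' @export
generate_artifact_train <- function(protocol, cfg, fs, amplitude_uV,
                                    tail_amp_uV = NULL) {
  w_s <- protocol$pulse_width_ms / 1000
  ipi <- 1 / protocol$frequency_hz
  if (w_s >= ipi)
    stop("pulse windows overlap: frequency too high for the pulse width")
  if (fs < 2 / w_s)
    stop("fs too low to represent the artifact pulse")
  n <- as.integer(round(protocol$duration_s * fs))
  n_pulses <- as.integer(round(protocol$frequency_hz * protocol$duration_s))
  pulse_times <- (seq_len(n_pulses) - 1) * ipi
  if (is.null(tail_amp_uV)) tail_amp_uV <- cfg$tail_amp_uV
  tau <- cfg$tail_tau_ms / 1000
  sig <- numeric(n)
  t_axis <- (seq_len(n) - 1) / fs
  if (amplitude_uV != 0) {
    for (tp in pulse_times) {
      idx <- which(t_axis >= tp & t_axis < min(tp + ipi, protocol$duration_s))
      td <- t_axis[idx] - tp
      wav <- numeric(length(td))
      eps <- 1e-9   # keep the half-open pulse interval robust to rounding
      wav[td < w_s / 2 - eps] <- -amplitude_uV
      wav[td >= w_s / 2 - eps & td < w_s - eps] <- amplitude_uV
      post <- td >= w_s - eps
      wav[post] <- tail_amp_uV * exp(-(td[post] - w_s) / tau)
      sig[idx] <- sig[idx] + wav
    }
  } else {
    pulse_times <- numeric(0)
  }
  list(signal = sig, pulse_times = pulse_times)
}
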