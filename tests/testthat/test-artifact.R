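test_that("spike detection counts pulses and respects the threshold", {
  fs <- 3000
  cfg <- synth_config(seed = 10)
  set.seed(10)
  baseline <- rnorm(2 * fs, sd = 20)
  resting_peak <- max(abs(baseline))
  bg <- rnorm(2 * fs, sd = 20)
  tr <- generate_artifact_train(stim_protocol(60), cfg, fs,
                                amplitude_uV = 12 * resting_peak,
                                tail_amp_uV = 60)
  det <- detect_spikes(bg + tr$signal, fs, baseline, threshold_k = 8)
  expect_length(det$spike_times_s, 120)
  expect_true(all(abs(det$spike_times_s -
                        tr$pulse_times[findInterval(det$spike_times_s,
                                                    tr$pulse_times)]) <
                    2e-3))
  # pure background: nothing to detect
  det0 <- detect_spikes(bg, fs, baseline, threshold_k = 8)
  expect_length(det0$spike_times_s, 0)
  expect_equal(det0$excised_fraction, 0)
  # sub-threshold artifacts (ratio 3 < k = 8) are not detected
  tr3 <- generate_artifact_train(stim_protocol(60), cfg, fs,
                                 amplitude_uV = 3 * sd(baseline),
                                 tail_amp_uV = 0)
  det3 <- detect_spikes(bg + tr3$signal, fs, baseline, threshold_k = 8)
  expect_length(det3$spike_times_s, 0)
  expect_error(detect_spikes(bg, fs, numeric(0)), "empty")
  expect_error(detect_spikes(bg, fs, baseline[1:100]), "0.5 s")
})

test_that("tail templates average the tails exactly and shrink noise", {
  fs <- 3000
  tail_len <- as.integer(round(0.015 * fs))
  tail <- 50 * exp(-(seq_len(tail_len) - 1) / fs / 0.005)
  times <- seq(0.1, 1.9, by = 1 / 60)[1:100]
  sig <- numeric(2 * fs + 100)
  off <- as.integer(round(0.0008 * fs))
  for (t in times) {
    i0 <- floor(t * fs + 0.5) + 1 + off
    sig[i0:(i0 + tail_len - 1)] <- sig[i0:(i0 + tail_len - 1)] + tail
  }
  det <- structure(list(spike_times_s = times, fs = fs),
                   class = "spike_detection")
  tmpl <- build_tail_templates(sig, det, stim_freq = 60, fs = fs,
                               tail_window_ms = 15)
  expect_equal(tmpl$waveform, tail, tolerance = 1e-12)
  expect_equal(tmpl$n_tails, 100)
  # residual RMS of a noisy template is about sigma / sqrt(n)
  for (seed in 1:3) {
    set.seed(seed)
    noisy <- sig + rnorm(length(sig), sd = 10)
    tm <- build_tail_templates(noisy, det, 60, fs, tail_window_ms = 15)
    res_rms <- sqrt(mean((tm$waveform - tail)^2))
    expect_lt(res_rms, 2.5 * 10 / sqrt(100))
    expect_gt(res_rms, 0.3 * 10 / sqrt(100))
  }
  expect_error(build_tail_templates(sig, det, 60, fs, times_s = times[1]),
               "need >= 10")
})

test_that("tail subtraction cancels injected tails and is identity for a zero template", {
  fs <- 3000
  set.seed(20)
  clean <- rnorm(fs, sd = 15)
  tail_len <- 30L
  tail <- 40 * exp(-(0:(tail_len - 1)) / 10)
  times <- c(0.05, 0.25, 0.61)
  off <- as.integer(round(0.0008 * fs))
  sig <- clean
  for (t in times) {
    i0 <- floor(t * fs + 0.5) + 1 + off
    sig[i0:(i0 + tail_len - 1)] <- sig[i0:(i0 + tail_len - 1)] + tail
  }
  tmpl <- structure(list(stim_frequency_hz = 60, waveform = tail,
                         n_tails = 99, offset_samples = off, fs = fs),
                    class = "artifact_template")
  out <- subtract_tails(sig, NULL, tmpl, times_s = times)
  expect_equal(out, clean, tolerance = 1e-9)
  tmpl0 <- tmpl; tmpl0$waveform <- numeric(tail_len)
  expect_identical(subtract_tails(sig, NULL, tmpl0, times_s = times), sig)
  # window past the signal end is truncated with a warning
  expect_warning(subtract_tails(sig, NULL, tmpl,
                                times_s = (length(sig) - 10) / fs),
                 "truncated")
})

test_that("excision leaves a constant signal unchanged and hits the stated fractions", {
  fs <- 3000
  const <- rep(42, 2 * fs)
  times <- seq(0.05, 1.95, by = 1 / 60)
  det <- structure(list(spike_times_s = times), class = "spike_detection")
  expect_equal(excise_and_fill(const, det, fs), const)
  # excised fraction: 120 pulses x 1.4 ms / 2000 ms, 80 x 1.4 / 2000
  set.seed(21)
  bg <- rnorm(2.2 * fs, sd = 10)
  baseline <- rnorm(2 * fs, sd = 10)
  cfg <- synth_config()
  for (spec in list(c(60, 120), c(40, 80))) {
    train <- generate_artifact_train(stim_protocol(spec[1]), cfg, fs,
                                     amplitude_uV = 2000, tail_amp_uV = 50)
    sig <- bg + c(train$signal, numeric(length(bg) - 2 * fs))
    d <- detect_spikes(sig, fs, baseline, threshold_k = 8, duration_s = 2)
    expect_length(d$spike_times_s, spec[2])
    expect_equal(d$excised_fraction, spec[2] * 1.4 / 2000,
                 tolerance = 1e-6)
  }
})

test_that("artifact-free sessions pass through rejection untouched", {
  cfg <- synth_config(seed = 31, n_trials = c(AI = 2, AT = 1), iti_s = 1)
  ses <- generate_session(cfg)
  res <- reject_artifacts(ses$recording, ses$events)
  expect_identical(res$recording$data, ses$recording$data)
  expect_equal(nrow(res$report), 0)
})

test_that("full rejection meets detection, excision and recovery contracts", {
  cfg <- quick_stim_cfg(seed = 42,
                        n_trials = c(AI = 1, S40 = 1, S60 = 1, S80 = 1))
  ses <- generate_session(cfg)
  res <- reject_artifacts(ses$recording, ses$events)
  gt <- ses$ground_truth
  fs <- cfg$fs_native

  # detection recall/precision vs ground-truth pulse times on the
  # stimulation-site channel
  for (i in which(!is.na(gt$stim_channel))) {
    truth <- gt$pulse_times[[i]]
    got <- res$report$n_detections[res$report$trial_id == i &
                                     res$report$channel ==
                                       gt$stim_channel[i]]
    expect_equal(got[1], length(truth))
  }

  # excised fraction: exact per frequency, paper bound for 40/60 Hz
  frac <- tapply(res$report$excised_fraction, res$report$state, max)
  expect_lte(frac[["S40"]], 0.09)
  expect_lte(frac[["S60"]], 0.09)
  expect_equal(unname(frac[["S80"]]), 160 * 1.4 / 2000, tolerance = 1e-6)

  # cleaned-vs-clean correlation during stimulation
  tr <- gt$trials[gt$trials$state %in% c("S40", "S60", "S80"), ]
  for (j in seq_len(nrow(tr))) {
    i0 <- floor(tr$anchor[j] * fs) + 1; i1 <- floor(tr$t_end[j] * fs)
    for (ci in 1:2)
      expect_gt(cor(res$recording$data[i0:i1, ci],
                    gt$clean[i0:i1, ci]), 0.95)
  }

  # idempotence: a second pass finds nothing and changes nothing
  res2 <- reject_artifacts(res$recording, ses$events)
  expect_identical(res2$recording$data, res$recording$data)
  expect_equal(sum(res2$report$n_detections), 0)
})
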