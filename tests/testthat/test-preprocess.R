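test_that("resampling to 512 Hz preserves DC, amplitude and length", {
  expect_equal(resample_512(rep(1, 6000), 3000), rep(1, 1024),
               tolerance = 1e-6)
  expect_length(resample_512(rnorm(6000), 3000), 1024)
  expect_length(resample_512(rnorm(7000), 3000), round(7000 * 512 / 3000))
  t <- (0:17999) / 3000
  y <- resample_512(sin(2 * pi * 10 * t), 3000)
  t2 <- (seq_along(y) - 1) / 512
  i <- 300:2700
  fit <- lm(y[i] ~ sin(2 * pi * 10 * t2[i]) + cos(2 * pi * 10 * t2[i]) - 1)
  expect_equal(sqrt(sum(coef(fit)^2)), 1, tolerance = 0.01)
  expect_error(resample_512(rnorm(100), 256), "at least")
})

test_that("band-pass filter meets its attenuation contracts", {
  fs <- 512
  tt <- (0:(20 * fs - 1)) / fs
  pass10 <- interior_peak(bandpass_1_200(sin(2 * pi * 10 * tt), fs), fs)
  expect_equal(pass10, 1, tolerance = 0.05)
  drift <- interior_peak(bandpass_1_200(sin(2 * pi * 0.1 * tt), fs), fs)
  expect_lt(drift, 10^(-20 / 20))          # >= 20 dB down at 0.1 Hz
  hi <- interior_peak(bandpass_1_200(sin(2 * pi * 250 * tt), fs), fs)
  expect_lt(hi, 10^(-20 / 20))             # >= 20 dB down at 250 Hz
  expect_equal(bandpass_1_200(numeric(4 * fs), fs), numeric(4 * fs))
  expect_error(bandpass_1_200(rnorm(1000), fs = 300), "too low")
})

test_that("linear detrending removes exactly the least-squares line", {
  t <- seq_len(5000)
  expect_equal(detrend_linear(3 + 0.25 * t), rep(0, 5000),
               tolerance = 1e-9)
  s <- sin(2 * pi * 7 * t / 1000)
  got <- detrend_linear(10 - 0.1 * t + s)
  expect_equal(got, detrend_linear(s), tolerance = 1e-9)
  once <- detrend_linear(rnorm(2000))
  expect_equal(detrend_linear(once), once, tolerance = 1e-9)
  # residual orthogonal to constant and ramp regressors
  expect_lt(abs(sum(once)), 1e-6 * sqrt(length(once)) * sd(once))
  expect_lt(abs(sum(once * seq_along(once))) /
              (sqrt(sum(seq_along(once)^2)) * sqrt(sum(once^2))), 1e-6)
})

test_that("notch and comb filters suppress their targets and spare the passband", {
  fs <- 512
  tt <- (0:(20 * fs - 1)) / fs
  expect_lt(interior_peak(notch_50(sin(2 * pi * 50 * tt), fs), fs),
            10^(-30 / 20))
  expect_equal(interior_peak(notch_50(sin(2 * pi * 10 * tt), fs), fs), 1,
               tolerance = 0.05)
  expect_lt(interior_peak(comb_stim(sin(2 * pi * 160 * tt), fs, 80), fs),
            10^(-30 / 20))
  expect_lt(interior_peak(comb_stim(sin(2 * pi * 80 * tt), fs, 80), fs),
            10^(-30 / 20))
  expect_equal(interior_peak(comb_stim(sin(2 * pi * 10 * tt), fs, 80), fs),
               1, tolerance = 0.05)
})

test_that("filters are zero-phase (no lag at the cross-correlation peak)", {
  fs <- 512
  tt <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 30 * tt)
  for (f in list(function(v) bandpass_1_200(v, fs),
                 function(v) notch_50(v, fs),
                 function(v) comb_stim(v, fs, 80))) {
    y <- f(x)
    cc <- ccf(x[fs:(9 * fs)], y[fs:(9 * fs)], lag.max = 5, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
  }
})

test_that("re-referencing subtracts the paired stimulation channel", {
  ch <- data.frame(name = c("L1", "LS"), hemisphere = "L",
                   role = c("record", "stim"),
                   paired_stim_channel = c("LS", NA))
  x <- rnorm(1000); s <- rnorm(1000)
  rec <- new_recording(cbind(x, numeric(1000)), 1000, ch)
  expect_equal(rereference_nearest_stim(rec)$data[, 1], x)
  rec2 <- new_recording(cbind(x + s, s), 1000, ch)
  out <- rereference_nearest_stim(rec2)
  expect_equal(out$data[, 1], x)          # common mode removed exactly
  expect_equal(out$data[, 2], s)          # stim channel passed through
  ch3 <- ch; ch3$paired_stim_channel <- c(NA, NA)
  rec3 <- new_recording(cbind(x, s), 1000, ch3)
  expect_error(rereference_nearest_stim(rec3), "paired_stim_channel")
})

test_that("channel rejection applies the strict 5x SD ratio rule", {
  fs <- 1000
  n <- 30 * fs
  set.seed(55)
  ev <- new_events(c(10, 12, 20, 22), rep(c("STIM_ON", "STIM_OFF"), 2),
                   c(1L, 1L, 2L, 2L), rep("S60", 4))
  base <- function() rnorm(n)
  noisy <- base()
  for (on in c(10, 20))
    noisy[(on * fs + 1):((on + 2) * fs)] <- rnorm(2 * fs, sd = 6)
  # sinusoid whose during-stimulation amplitude is exactly 5x; windows
  # cover whole cycles, so the pooled SD ratio is exactly 5
  tt <- (seq_len(n) - 1) / fs
  exact5 <- sin(2 * pi * 5 * tt)
  for (on in c(10, 20)) {
    seg <- (on * fs + 1):((on + 2) * fs)
    exact5[seg] <- 5 * exact5[seg]
  }
  ch <- data.frame(name = c("ok", "noisy", "edge"), hemisphere = "L",
                   role = "record", paired_stim_channel = NA)
  rec <- new_recording(cbind(base(), noisy, exact5), fs, ch)
  res <- reject_noisy_channels(rec, ev, ratio = 5)
  expect_identical(res$rejected, "noisy")
  expect_true(res$ratios[["ok"]] > 0.8 && res$ratios[["ok"]] < 1.2)
  expect_equal(res$ratios[["edge"]], 5, tolerance = 1e-9)
  expect_identical(res$recording$channels$name, c("ok", "edge"))
  # all channels rejected is fatal
  ch2 <- data.frame(name = c("a", "b"), hemisphere = "L", role = "record",
                    paired_stim_channel = NA)
  rec_all <- new_recording(cbind(noisy, 2 * noisy), fs, ch2)
  expect_error(reject_noisy_channels(rec_all, ev), "cannot proceed")
})

test_that("the full chain preserves the designed band-power ordering", {
  for (seed in 1:3) {
    cfg <- quick_stim_cfg(seed = seed,
                          n_trials = c(AI = 1, AT = 1, S40 = 1, S60 = 1,
                                       S80 = 1))
    ses <- generate_session(cfg)
    cleaned <- reject_artifacts(ses$recording, ses$events)$recording
    pp <- preprocess_recording(cleaned, ses$events)
    tab <- build_band_power_table(list(list(subject = "s1",
                                            recording = pp$recording,
                                            events = ses$events)))
    agg <- aggregate(log_power ~ state + band, data = as.data.frame(tab),
                     FUN = mean)
    gains <- cfg$band_gains
    bw <- with(band_specs(), hi - lo + 1)
    names(bw) <- band_specs()$name
    for (st in rownames(gains)) {
      designed <- names(which.max(gains[st, ]^2 / bw))
      got <- agg[agg$state == st, ]
      expect_identical(got$band[which.max(got$log_power)], designed,
                       label = paste("state", st, "seed", seed))
    }
  }
})
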