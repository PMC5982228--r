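# spectral amplitude of a single frequency line
.tone_amp <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  2 * abs(mean(x * exp(-2i * pi * f * t)))
}

test_that("baseline detrend removes offsets and slow wander", {
  fs <- 200
  const <- multilead_signal(matrix(2.5, nrow = 10 * fs, ncol = 1), fs)
  out <- detrend_baseline(const)
  expect_lt(max(abs(out$samples)), 1e-8)

  zero <- multilead_signal(matrix(0, nrow = 10 * fs, ncol = 2), fs)
  expect_equal(detrend_baseline(zero)$samples, zero$samples)

  rec <- clean_rec(60)
  t <- (seq_len(n_samples(rec$signal)) - 1) / fs
  wander <- 1.5 * sin(2 * pi * 0.2 * t)
  noisy <- rec$signal
  noisy$samples[, 1] <- noisy$samples[, 1] + wander
  out <- detrend_baseline(noisy, knot_s = 1)
  a_before <- .tone_amp(noisy$samples[, 1], 0.2, fs)
  a_after <- .tone_amp(out$samples[, 1], 0.2, fs)
  expect_lt(a_after, 0.10 * a_before)
})

test_that("detrend falls back to mean subtraction on very short records", {
  short <- multilead_signal(matrix(1:100 / 100 + 3, ncol = 1), fs = 100)
  expect_warning(out <- detrend_baseline(short), "knots")
  expect_lt(abs(mean(out$samples)), 1e-10)
})

test_that("powerline notch kills the mains tone but not the QRS band", {
  fs <- 360
  t <- (0:(10 * fs - 1)) / fs
  tone50 <- multilead_signal(sin(2 * pi * 50 * t), fs)
  out <- notch_powerline(tone50, 50, 2)
  # steady-state response: measure away from the zero-phase transients
  interior <- (2 * fs):(8 * fs)
  expect_lt(sqrt(mean(out$samples[interior, 1]^2)),
            0.05 * sqrt(mean(tone50$samples[interior, 1]^2)))

  tone10 <- multilead_signal(sin(2 * pi * 10 * t), fs)
  out10 <- notch_powerline(tone10, 50, 2)
  expect_lt(abs(sqrt(mean(out10$samples[interior, 1]^2)) /
                  sqrt(mean(tone10$samples[interior, 1]^2)) - 1), 0.02)

  zero <- multilead_signal(matrix(0, nrow = fs, ncol = 1), fs)
  expect_equal(notch_powerline(zero)$samples, zero$samples)
  expect_error(notch_powerline(multilead_signal(sin(t), fs = 90), f0 = 50),
               "Nyquist")
})

test_that("low-pass has unit DC gain and the expected stop/pass behavior", {
  fs <- 360
  const <- multilead_signal(matrix(1, nrow = 5 * fs, ncol = 1), fs)
  expect_lt(max(abs(lowpass(const, 25)$samples - 1)), 1e-6)

  t <- (0:(10 * fs - 1)) / fs
  hi <- multilead_signal(sin(2 * pi * 60 * t), fs)
  att60 <- .tone_amp(lowpass(hi, 25)$samples[, 1], 60, fs)
  expect_lt(20 * log10(att60 / 1), -20)     # > 20 dB down

  lo <- multilead_signal(sin(2 * pi * 5 * t), fs)
  att5 <- .tone_amp(lowpass(lo, 25)$samples[, 1], 5, fs)
  expect_gt(20 * log10(att5), -1)           # < 1 dB loss
  expect_error(lowpass(lo, 200), "fs/2")
})

test_that("motion suppression touches only high-variance bursts", {
  fs <- 200
  t <- (0:(60 * fs - 1)) / fs
  sine <- multilead_signal(sin(2 * pi * 1.3 * t), fs)
  expect_identical(suppress_motion_artifacts(sine)$samples, sine$samples)

  zero <- multilead_signal(matrix(0, nrow = fs * 10, ncol = 1), fs)
  expect_equal(suppress_motion_artifacts(zero)$samples, zero$samples)

  rec <- clean_rec(60)
  burst <- rec$signal
  w <- 30 * fs + seq_len(fs)        # 1-s burst at t = 30 s
  set.seed(99)
  burst$samples[w, 1] <- burst$samples[w, 1] + 10 * rnorm(fs)
  out <- suppress_motion_artifacts(burst)
  expect_gt(max(abs(burst$samples[w, 1])) / max(abs(out$samples[w, 1])), 5)
  guard <- c((min(w) - 0.2 * fs):(max(w) + 0.2 * fs))
  outside <- setdiff(seq_len(n_samples(burst)), guard)
  expect_identical(out$samples[outside, 1], burst$samples[outside, 1])
})

test_that("the full preprocessing chain preserves QRS fiducials", {
  fs <- 200
  zero <- multilead_signal(matrix(0, nrow = 20 * fs, ncol = 2), fs)
  expect_lt(max(abs(preprocess_record(zero)$samples)), 1e-8)

  rec <- clean_rec(60)
  clean <- preprocess_record(rec$signal)
  r <- rec$annotations$indices
  # amplitude preserved within 15% and fiducial shift at most 1 sample
  for (i in r) {
    win <- (i - 3):(i + 3) + 1
    j <- win[which.max(clean$samples[win, 1])]
    expect_lte(abs(j - 1 - i), 1)
    expect_lt(abs(clean$samples[j, 1] / rec$signal$samples[i + 1, 1] - 1),
              0.15)
  }
})

test_that("preprocessing raises the SNR of a noisy record", {
  cfg <- synth_config(duration_s = 60, seed = 31,
                      noise = list(list(type = "muscle", snr_db = 6),
                                   list(type = "powerline", snr_db = 3),
                                   list(type = "baseline_wander",
                                        snr_db = 3)))
  noisy <- synth_ecg(cfg)
  ref <- clean_rec(60, seed = 31)$signal   # same seed -> same clean part
  out <- preprocess_record(noisy$signal)
  ref_p <- preprocess_record(ref)
  err_before <- mean((noisy$signal$samples - ref$samples)^2)
  err_after <- mean((out$samples - ref_p$samples)^2)
  snr_gain <- 10 * log10(err_before / err_after)
  expect_gt(snr_gain, 3)
})

test_that("notch and low-pass are idempotent on passband content", {
  # well inside the passband a second application must change nothing;
  # near the band edge Butterworth roll-off attenuates on every pass,
  # so the property is asserted for in-band tones
  fs <- 200
  t <- (0:(30 * fs - 1)) / fs
  mix <- multilead_signal(sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 5 * t) +
                            0.3 * sin(2 * pi * 10 * t), fs)
  once <- lowpass(notch_powerline(mix), 25)
  twice <- lowpass(notch_powerline(once), 25)
  interior <- (2 * fs):(28 * fs)
  rel <- sqrt(mean((twice$samples[interior, 1] - once$samples[interior, 1])^2)) /
    sqrt(mean(once$samples[interior, 1]^2))
  expect_lt(rel, 0.01)
})
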