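test_that("apply_calibration is the stated affine map", {
  line <- calibration_line(5, 0)
  expect_equal(apply_calibration(rep(0, 10), line, fs = 100)$samples,
               rep(0, 10))
  line2 <- calibration_line(2, 1)
  expect_equal(apply_calibration(c(1, 2), line2, fs = 100)$samples, c(3, 5))
  expect_error(calibration_line(0), "slope")
  # affine identity: apply(a x + b y) = a apply(x) + b apply(y) - (a+b-1) c
  set.seed(1)
  for (i in 1:5) {
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    x <- rnorm(20); y <- rnorm(20)
    lhs <- apply_calibration(a * x + b * y, line2, fs = 1)$samples
    rhs <- a * apply_calibration(x, line2, fs = 1)$samples +
      b * apply_calibration(y, line2, fs = 1)$samples -
      (a + b - 1) * line2$intercept
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("fit_calibration_line recovers known lines", {
  l <- fit_calibration_line(c(0, 10), c(0, 1))
  expect_equal(l$slope, 10)
  expect_equal(l$intercept, 0)
  # five-point pressure calibration reproduces the reference points exactly
  press <- c(0, 5, 10, 15, 20)
  volts <- (press - 1.5) / 4.1
  l2 <- fit_calibration_line(press, volts)
  expect_equal(apply_calibration(volts, l2, fs = 1, channel = "IOP")$samples,
               press, tolerance = 1e-10)
  expect_error(fit_calibration_line(c(0, 5), c(1, 1)), "degenerate")
  # noisy line: compare against the closed-form least-squares oracle
  set.seed(42)
  v <- runif(50, 0, 2)
  u <- 9.8 * v + 0.7 + rnorm(50, 0, 0.1)
  l3 <- fit_calibration_line(u, v)
  oracle_slope <- cov(v, u) / var(v)
  expect_equal(l3$slope, oracle_slope, tolerance = 1e-12)
  expect_lt(abs(l3$slope - 9.8), 0.1)
})

test_that("resample preserves tones, DC, and the length contract", {
  fs1 <- 11025
  x <- sin(2 * pi * 100 * seq(0, 1, by = 1 / fs1))
  sig <- calibrated_signal(x, fs1, "ACC")
  out <- resample_signal(sig, 20000)
  expect_equal(out$fs, 20000)
  expect_lte(abs(length(out$samples) - round(length(x) * 20000 / 11025)), 1)
  sp <- Mod(stats::fft(out$samples))
  n <- length(out$samples)
  peak_f <- (which.max(sp[1:(n %/% 2)]) - 1) * 20000 / n
  expect_lt(abs(peak_f - 100), 20000 / n + 1e-9)  # within one bin
  # DC preservation is exact away from the FIR edge transients
  const <- resample_signal(calibrated_signal(rep(3.3, 500), fs1, "ACC"), 20000)
  interior <- const$samples[40:(length(const$samples) - 40)]
  expect_equal(max(abs(interior - 3.3)), 0, tolerance = 1e-9)
  # up then down returns the original within 1e-3 relative RMS
  back <- resample_signal(out, fs1)
  m <- min(length(x), length(back$samples))
  rel <- sqrt(mean((x[1:m] - back$samples[1:m])^2)) / sqrt(mean(x^2))
  expect_lt(rel, 1e-3)
})

test_that("align_acc_to_mic finds planted lags", {
  fs <- 2000
  set.seed(2)
  base <- subpress:::fft_bandpass(rnorm(6000), fs, 50, 500)
  mic <- calibrated_signal(base, fs, "MIC")
  expect_equal(align_acc_to_mic(mic, mic), 0)
  delayed <- calibrated_signal(apply_lag(base, -100), fs, "ACC")
  expect_equal(align_acc_to_mic(delayed, mic), 100)
  expect_error(align_acc_to_mic(calibrated_signal(rep(0, 100), fs, "ACC"),
                                calibrated_signal(rep(0, 100), fs, "MIC")),
               "silent")
  # shared periodic component + independent noise at ~10 dB SNR, shift 37
  t <- seq_len(6000) / fs
  shared <- sin(2 * pi * 90 * t) + 0.5 * sin(2 * pi * 217 * t)
  a <- apply_lag(shared, -37) + rnorm(6000, 0, sqrt(mean(shared^2)) / 3.16)
  b <- shared + rnorm(6000, 0, sqrt(mean(shared^2)) / 3.16)
  expect_equal(align_acc_to_mic(calibrated_signal(a, fs, "ACC"),
                                calibrated_signal(b, fs, "MIC")), 37)
  # property: recovered lag equals the planted lag on random band-limited
  # signals for |k| < n/4
  for (k in c(-311, -40, 13, 250)) {
    y <- apply_lag(base, -k)
    expect_equal(align_acc_to_mic(calibrated_signal(y, fs, "ACC"), mic), k)
  }
})

test_that("wav round trip preserves signal and metadata", {
  sig <- calibrated_signal(sin(2 * pi * 50 * seq(0, 0.1, by = 1 / 4000)),
                           4000, "ACC")
  p <- file.path(tempdir(), "acc_test.wav")
  write_wav_signal(sig, p)
  back <- read_wav_signal(p)
  expect_equal(back$samples, sig$samples, tolerance = 1e-7)
  expect_equal(back$fs, 4000)
  expect_equal(back$channel, "ACC")
  expect_equal(back$units, "cm/s2")
  # pcm16 path
  write_wav_signal(sig, p, format = "pcm16")
  back16 <- read_wav_signal(p)
  expect_equal(back16$samples, sig$samples, tolerance = 1e-3)
  unlink(c(p, paste0(p, ".json")))
})
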