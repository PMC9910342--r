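test_that("frame_rms closed forms and scaling monotonicity", {
  fs <- 10000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)  # whole cycles of 100 Hz
  expect_equal(frame_rms(2.5 * sin(2 * pi * 100 * t)), 2.5 / sqrt(2),
               tolerance = 1e-6)
  expect_equal(frame_rms(rep(0, 10)), 0)
  expect_equal(frame_rms(c(3, 4)), sqrt(12.5))
  set.seed(1)
  x <- rnorm(100)
  for (k in c(0.5, 2, 7)) expect_equal(frame_rms(k * x), k * frame_rms(x))
})

test_that("spl_from_mic reference levels and gain law", {
  n <- 1000
  expect_equal(spl_from_mic(rep(20e-6, n)), 0)
  expect_equal(spl_from_mic(rep(0.2, n)), 80)
  expect_equal(spl_from_mic(rep(2, n)), 100)
  expect_error(spl_from_mic(rep(0, n)), "zero-energy")
  set.seed(2)
  x <- rnorm(n)
  for (k in c(0.1, 3)) {
    expect_equal(spl_from_mic(k * x), spl_from_mic(x) + 20 * log10(k),
                 tolerance = 1e-10)
  }
})

test_that("f0_autocorrelation: pure tones, octave correction, noise", {
  fs <- 20000
  t <- seq(0, 0.05, by = 1 / fs)
  p <- f0_autocorrelation(sin(2 * pi * 200 * t), fs)
  expect_lt(abs(p$f0 - 200), 2)
  expect_true(p$voiced)
  # boosted second harmonic: fundamental 100 Hz, 2nd harmonic 3x -> 100 Hz
  pb <- f0_autocorrelation(sin(2 * pi * 100 * t) + 3 * sin(2 * pi * 200 * t),
                           fs)
  expect_lt(abs(pb$f0 - 100), 2)
  # white noise is unvoiced across seeds
  unvoiced <- vapply(1:100, function(s) {
    set.seed(s)
    !f0_autocorrelation(rnorm(round(0.05 * fs)), fs)$voiced
  }, logical(1))
  expect_gte(mean(unvoiced), 0.98)
})

test_that("f0 error < 1% over random harmonic signals in 80-400 Hz", {
  fs <- 11025
  n <- round(0.05 * fs)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    f0 <- runif(1, 80, 400)
    t <- seq_len(n) / fs
    amps <- c(1, runif(3, 0.1, 0.8))
    x <- rowSums(sapply(1:4, function(k)
      amps[k] * sin(2 * pi * k * f0 * t + runif(1, 0, 2 * pi))))
    abs(f0_autocorrelation(x, fs)$f0 - f0) / f0
  }, numeric(1))
  expect_lt(max(errs), 0.01)
})

test_that("cpp separates periodic from jittered and noisy windows", {
  fs <- 20000
  n <- round(0.055 * fs)
  wins <- lapply(1:50, function(s) {
    clean <- lf_pulse_train(100, 60, 200, 300, duration = 0.06, fs = fs,
                            jitter = 0, seed = s)$flow[1:n]
    jit <- lf_pulse_train(100, 60, 200, 300, duration = 0.06, fs = fs,
                          jitter = 2, seed = s)$flow[1:n]
    set.seed(s)
    list(clean = cpp(clean, fs), jit = cpp(jit, fs),
         noise = cpp(rnorm(n), fs))
  })
  dclean <- vapply(wins, `[[`, numeric(1), "clean")
  djit <- vapply(wins, `[[`, numeric(1), "jit")
  dnoise <- vapply(wins, `[[`, numeric(1), "noise")
  # sign test: clean > jittered in essentially all paired draws
  expect_gte(mean(dclean > djit), 0.95)
  expect_gt(mean(dclean) - mean(dnoise), 5)
  # gain invariance
  x <- lf_pulse_train(120, 60, 200, 300, duration = 0.06, fs = fs)$flow[1:n]
  expect_equal(cpp(2 * x, fs), cpp(x, fs), tolerance = 1e-6)
})

test_that("spl mapping recovery and application", {
  # noiseless planted mapping: exact
  acc_db <- seq(-10, 20, length.out = 12)
  m <- fit_spl_mapping(acc_db, 1.0 * acc_db + 60)
  expect_equal(m$slope, 1.0, tolerance = 1e-12)
  expect_equal(m$intercept, 60, tolerance = 1e-12)
  expect_equal(acc_to_spl(m, 10^(5 / 20)), 65, tolerance = 1e-10)
  # noisy: slope within 0.05 of planted (closed-form regression oracle)
  set.seed(9)
  slopes <- vapply(1:50, function(s) {
    set.seed(s)
    a <- runif(40, -15, 15)
    spl <- 0.9 * a + 62 + rnorm(40, 0, 1)
    fit_spl_mapping(a, spl)$slope
  }, numeric(1))
  expect_lt(abs(median(slopes) - 0.9), 0.05)
  # residual RMSE consistent with regression theory (sigma = 1, n = 40)
  set.seed(10)
  a <- runif(40, -15, 15)
  spl <- 0.9 * a + 62 + rnorm(40)
  m2 <- fit_spl_mapping(a, spl)
  rmse <- sqrt(mean((acc_to_spl(m2, 10^(a / 20)) - spl)^2))
  expect_lte(rmse, 1 * sqrt(1 + 2 / 40) * 1.3)
  # narrow span flags unreliable
  expect_warning(fit_spl_mapping(seq(0, 1, length.out = 6),
                                 seq(60, 65, length.out = 6)), "unreliable")
})
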