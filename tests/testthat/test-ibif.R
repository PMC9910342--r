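test_that("ibif_transfer is invertible in band and follows resonance physics", {
  ip <- ibif_params()
  H <- ibif_transfer(ip, 20000, 8192)
  f <- (0:8191) * 20000 / 8192
  inband <- f >= 50 & f <= 4000
  expect_true(all(Mod(H[inband]) > 0))
  # doubling skin inertance lowers the resonance peak by ~sqrt(2) (lightly
  # damped so the amplitude-resonance shift is negligible)
  pk <- function(m) {
    Hm <- ibif_transfer(ibif_params(skin_inertance = m,
                                    skin_resistance = 200), 20000, 40000)
    fr <- (0:39999) * 20000 / 40000
    sel <- fr >= 30 & fr <= 1500
    fr[sel][which.max(Mod(Hm[sel]))]
  }
  ratio <- pk(1) / pk(2)
  expect_lt(abs(ratio - sqrt(2)), 0.02 * sqrt(2))
  expect_error(ibif_params(skin_inertance = -1), "positive")
  expect_error(ibif_params(acc_position = 15, tracheal_length = 12), "below")
})

test_that("forward/inverse round trip recovers the waveform and features", {
  cs <- ibif_roundtrip_case()
  g <- inverse_filter(cs$acc, cs$params, fs = 20000)
  # zero mean
  expect_lt(abs(mean(g$flow)), 1e-6 * diff(range(g$flow)))
  ref <- subpress:::fft_bandpass(cs$train$flow - mean(cs$train$flow),
                                 20000, 50, 4000)
  expect_gte(corr_trim(g$flow, ref, 20000, 130), 0.99)
  # amplitude linearity
  g2 <- inverse_filter(2 * cs$acc, cs$params, fs = 20000)
  expect_equal(g2$flow, 2 * g$flow, tolerance = 1e-9)
  # planted OQ recovered within 5 points
  td <- time_domain_features(g)
  expect_lt(abs(td$oq - 62), 5)
  # too-short segment errors
  expect_error(inverse_filter(cs$acc[1:200], cs$params, fs = 20000, f0 = 130),
               "insufficient")
})

test_that("round trip holds across random parameter draws", {
  set.seed(4)
  b <- default_ibif_bounds()
  for (i in 1:5) {
    v <- runif(5, b[1, ], b[2, ])
    if (v[5] >= v[4]) v[5] <- v[4] * 0.8
    ip <- ibif_params(v[1], v[2], v[3], v[4], v[5])
    f0 <- runif(1, 90, 220)
    tr <- lf_pulse_train(f0, runif(1, 50, 70), 200, 300,
                         duration = 0.15, fs = 20000, jitter = 0.3, seed = i)
    acc <- forward_ibif(tr$flow, 20000, ip)
    g <- inverse_filter(acc, ip, fs = 20000)
    ref <- subpress:::fft_bandpass(tr$flow - mean(tr$flow), 20000, 50, 4000)
    expect_gte(corr_trim(g$flow, ref, 20000, f0), 0.99)
  }
})

test_that("time_domain_features on constructed pulse shapes", {
  fs <- 20000
  # symmetric triangular pulse occupying exactly half of each period
  np <- 200  # 100 Hz
  cyc <- numeric(np)
  half <- np / 2
  cyc[(half + 1):(half + half / 2)] <- seq(0, 300,
                                           length.out = half / 2)
  cyc[(half + half / 2 + 1):np] <- seq(300, 0,
                                       length.out = half / 2 + 1)[-1]
  # place open phase at the cycle end (closure = cycle boundary)
  flow <- rep(cyc, 12)
  g <- structure(list(flow = flow - mean(flow), fs = fs, f0 = 100),
                 class = "glottal_waveform")
  td <- time_domain_features(g)
  expect_equal(td$acfl, 300, tolerance = 0.02 * 300)
  expect_lt(abs(td$oq - 50), 5)   # 10%-threshold opening detection: ~47.5
  expect_lt(abs(td$sq - 100), 15)
  # scaling: acfl, mfdr double; oq, sq, naq unchanged
  g2 <- g; g2$flow <- 2 * g$flow
  td2 <- time_domain_features(g2)
  expect_equal(td2$acfl, 2 * td$acfl, tolerance = 1e-9)
  expect_equal(td2$mfdr, 2 * td$mfdr, tolerance = 1e-9)
  expect_equal(td2$oq, td$oq, tolerance = 1e-9)
  expect_equal(td2$sq, td$sq, tolerance = 1e-9)
  expect_equal(td2$naq, td$naq, tolerance = 1e-9)
  # LF-style train with planted OQ/SQ
  tr <- lf_pulse_train(120, 60, 200, 300, duration = 0.2, fs = fs)
  gtr <- structure(list(flow = tr$flow - mean(tr$flow), fs = fs, f0 = 120),
                   class = "glottal_waveform")
  tdtr <- time_domain_features(gtr)
  expect_lt(abs(tdtr$oq - 60), 5)
  expect_lt(abs(tdtr$sq - 200), 15 + 15)  # opening threshold biases SQ down
  expect_equal(tdtr$acfl, 300, tolerance = 0.01 * 300)
  # open + closed time sum to the period within 1%
  expect_lt(abs(tdtr$f0 - 120) / 120, 0.01)
})

test_that("spectral_features: harmonic ratios", {
  fs <- 20000
  t <- seq_len(round(0.2 * fs)) / fs
  # pure sine: H2 at the floor, strongly negative HRF
  gs <- structure(list(flow = sin(2 * pi * 150 * t), fs = fs, f0 = 150),
                  class = "glottal_waveform")
  sp <- spectral_features(gs)
  expect_gte(sp$h1h2, 40)
  expect_lt(sp$hrf, -30)
  # two tones with amplitudes 1.0 and 0.5 -> 6.02 dB
  g2 <- structure(list(flow = sin(2 * pi * 150 * t) +
                         0.5 * sin(2 * pi * 300 * t + 0.7),
                       fs = fs, f0 = 150), class = "glottal_waveform")
  expect_lt(abs(spectral_features(g2)$h1h2 - 20 * log10(2)), 0.1)
  # harmonics above Nyquist are flagged and skipped
  gh <- structure(list(flow = sin(2 * pi * 150 * seq_len(1000) / 2000),
                       fs = 2000, f0 = 150), class = "glottal_waveform")
  sph <- spectral_features(gh)
  expect_true(sph$flag_nyquist)
  expect_lt(sph$n_harmonics_used, 8)
})

test_that("validity_filter applies the four physiological rules", {
  base <- data.frame(acfl = 200, mfdr = 300, oq = 55)
  expect_true(validity_filter(base, 180)$keep)
  v1 <- validity_filter(data.frame(acfl = 0.5, mfdr = 300, oq = 55), 180)
  expect_false(v1$keep); expect_equal(v1$reasons, "ACFL")
  v2 <- validity_filter(base, 600)
  expect_false(v2$keep); expect_equal(v2$reasons, "F0")
  v3 <- validity_filter(data.frame(acfl = 0.5, mfdr = 0.5, oq = 140), 600)
  expect_setequal(v3$reasons, c("ACFL", "MFDR", "OQ", "F0"))
  # keep-rate is 1 on a noiseless modal session with f0 <= 400
  lab <- lab_noiseless()
  ft <- process_lab_session(lab$ses, lab$spec$ibif_true,
                            use_truth_segments = TRUE)
  expect_true(all(ft$valid))
})

test_that("PSO respects bounds, is deterministic, and reaches the planted objective", {
  cs <- ibif_roundtrip_case()
  flow_ch <- cs$train$flow + 80  # oral airflow has a DC offset
  fit <- fit_ibif_pso(cs$acc, flow_ch, fs = 20000, seed = 42, max_iter = 40,
                      swarm_size = 20)
  b <- default_ibif_bounds()
  v <- unlist(fit$params)
  expect_true(all(v >= b[1, ] & v <= b[2, ]))
  fit2 <- fit_ibif_pso(cs$acc, flow_ch, fs = 20000, seed = 42, max_iter = 40,
                       swarm_size = 20)
  expect_identical(unlist(fit$params), unlist(fit2$params))
  ref <- subpress:::fft_bandpass(flow_ch - mean(flow_ch), 20000, 50, 1100)
  obj_true <- subpress:::ibif_objective_vec(unlist(cs$params), cs$acc, ref,
                                            20000)
  expect_lte(fit$objective, obj_true * 1.01)
})
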