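test_that("frame_stream tiles the stream with 50-ms frames", {
  fs <- 11025
  s1 <- frame_stream(calibrated_signal(rep(0, fs), fs, "ACC"))
  expect_equal(s1$n_frames, 20)
  s2 <- frame_stream(calibrated_signal(rep(0, round(1.04 * fs)), fs, "ACC"))
  expect_equal(s2$n_frames, 20)  # trailing 40 ms dropped
  expect_equal(s1$starts, (0:19) * s1$frame_len)
  expect_equal(diff(s1$starts), rep(s1$frame_len, 19))  # no gaps or overlap
})

test_that("is_voiced is the conjunction of the five inclusive ranges", {
  c0 <- vad_criteria()
  f <- function(spl = 80, f0 = 150, ac = 0.8, sub = 0.5, lh = 30) {
    data.frame(spl = spl, f0 = f0, autocorr_peak = ac,
               subharmonic_peak = sub, lh_ratio = lh)
  }
  expect_true(is_voiced(f(), c0))
  expect_false(is_voiced(f(spl = 40), c0))
  expect_false(is_voiced(f(ac = 0.59), c0))
  expect_false(is_voiced(f(f0 = NA), c0))
  # monotonicity: tightening any range never increases the voiced count
  set.seed(11)
  frames <- f(spl = runif(200, 30, 140), f0 = runif(200, 50, 1100),
              ac = runif(200), sub = runif(200), lh = runif(200, 10, 60))
  n0 <- sum(is_voiced(frames, c0))
  tighter <- list(vad_criteria(spl = c(50, 120)),
                  vad_criteria(f0 = c(90, 800)),
                  vad_criteria(autocorr_peak = c(0.7, 1)),
                  vad_criteria(subharmonic_peak = c(0.4, 1)),
                  vad_criteria(lh_ratio = c(25, 45)))
  for (ct in tighter) expect_lte(sum(is_voiced(frames, ct)), n0)
  expect_error(vad_criteria(spl = c(100, 50)), "range")
})

test_that("process_day gates Ps estimates on voicing and validity", {
  ds <- day_short()
  rec <- ds$records
  truth <- ds$day$truth
  # voiced + unvoiced = total
  expect_equal(sum(rec$voiced) + sum(!rec$voiced), nrow(rec))
  # voiced-flag agreement with generator truth
  expect_gte(mean(rec$voiced == truth$voiced), 0.98)
  # frames the generator marks silent carry no Ps estimate
  expect_true(all(is.na(rec$ps_est[!truth$voiced])))
  # ps_est present => voiced and valid
  expect_true(all(rec$voiced[!is.na(rec$ps_est)]))
  expect_true(all(rec$valid[!is.na(rec$ps_est)]))
  # per-frame Ps error is small under matched conditions
  vv <- rec$voiced & rec$valid & truth$voiced
  expect_lt(median(abs(rec$ps_est[vv] - truth$ps_true[vv])), 1)
  expect_error(process_day(ds$day$acc, NULL, ds$spec$ibif_true),
               "configuration")
})

test_that("summarize_day matches a brute-force oracle", {
  # constructed multiset: Ps 5 x100, 10 x100, 15 x100 frames
  ps <- rep(c(5, 10, 15), each = 100)
  rec <- data.frame(frame = seq_along(ps) - 1, t_start = (seq_along(ps) - 1) *
                      0.05, ps_est = ps, voiced = TRUE, valid = TRUE)
  s <- summarize_day(rec)
  expect_equal(s$ps$mean, 10)
  expect_equal(s$ps$p5, 5)
  expect_equal(s$ps$p95, 15)
  expect_equal(s$phonation_pct, 100)
  expect_equal(s$phonation_time_cum_s, 15)
  # all-unvoiced stream
  rec0 <- data.frame(frame = 0:9, t_start = (0:9) * 0.05,
                     ps_est = NA_real_, voiced = FALSE, valid = FALSE)
  s0 <- summarize_day(rec0)
  expect_equal(s0$phonation_pct, 0)
  expect_null(s0$ps)
  # symmetric sample: skewness 0
  xs <- c(-3, -1, 0, 1, 3)
  recs <- data.frame(frame = 0:4, t_start = (0:4) * 0.05, ps_est = xs,
                     voiced = TRUE, valid = TRUE)
  expect_lt(abs(summarize_day(recs)$ps$skewness), 1e-9)
})

test_that("rolling_profile window accounting", {
  nfr <- 12000  # 10 minutes
  rec <- data.frame(frame = seq_len(nfr) - 1,
                    t_start = (seq_len(nfr) - 1) * 0.05,
                    ps_est = 8, voiced = TRUE, valid = TRUE)
  prof <- rolling_profile(rec)
  full <- prof[!prof$truncated, ]
  expect_equal(nrow(full), 11)       # starts 0, 30, ..., 300 s
  expect_equal(diff(full$t_start), rep(30, 10))
  expect_true(any(prof$truncated))
  expect_true(all(prof$pct_phonation == 100))
  expect_true(all(full$median == 8))
})

test_that("ambulatory IBIF segment selection picks max-Ps comfortable /a/", {
  seg <- data.frame(vowel = c("a", "a", "i", "a"),
                    pitch = c("comfortable", "comfortable", "comfortable",
                              "higher"),
                    ps_ref = c(9, 14, 20, 22))
  expect_equal(select_ambulatory_ibif_segment(seg), 2)
  expect_error(select_ambulatory_ibif_segment(
    data.frame(vowel = "i", pitch = "comfortable", ps_ref = 5)), "no /a/")
})
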