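# Shared fixtures, memoized so expensive synthetic sessions are built once per
# test run. Everything is generated in code; no binary fixtures.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A noiseless single-condition laboratory session: exact planted recovery.
noiseless_spec <- function(...) {
  participant_spec(seed = 7, n_trials = 1, vowels = "a",
                   pitch_factors = c(comfortable = 1),
                   oq_by_pitch = c(comfortable = 60), n_syllables = 8,
                   iop_sigma = 0, acc_snr_db = Inf, aspiration_db = -Inf, ...)
}

lab_noiseless <- function() {
  fixture("lab_noiseless", function() {
    spec <- noiseless_spec()
    list(spec = spec, ses = synthesize_lab_session(spec))
  })
}

# A realistic noisy session across all conditions (2 x 3 x 3 protocol).
lab_noisy <- function() {
  fixture("lab_noisy", function() {
    spec <- participant_spec(seed = 3)
    ses <- synthesize_lab_session(spec)
    list(spec = spec, ses = ses,
         features = process_lab_session(ses, spec$ibif_true))
  })
}

# A short simulated day (72 s) with the default participant.
day_short <- function() {
  fixture("day_short", function() {
    spec <- participant_spec(seed = 5)
    day <- synthesize_day(spec, duration_h = 0.02, voiced_fraction = 0.3)
    model <- structure(list(slope = spec$ps_slope,
                            intercept = spec$ps_intercept,
                            n = 10L, rmse_train = 0),
                       class = "ps_line_model")
    rec <- process_day(day$acc, day$spl_mapping_true, spec$ibif_true, model)
    list(spec = spec, day = day, model = model, records = rec)
  })
}

# A glottal pulse train forward-filtered through known IBIF parameters.
ibif_roundtrip_case <- function() {
  fixture("ibif_roundtrip", function() {
    ip <- ibif_params(2.2, 1800, 1.1e6, 11, 4.5)
    tr <- lf_pulse_train(130, 62, 200, 350, duration = 0.25, fs = 20000,
                         jitter = 0.3, seed = 3)
    acc <- forward_ibif(tr$flow, 20000, ip)
    list(params = ip, train = tr, acc = acc)
  })
}

# Correlation excluding segment-edge filter transients (inverse filtering of
# a finite segment is meaningless within ~2 periods of the edges).
corr_trim <- function(a, b, fs, f0, periods = 2) {
  tr <- round(periods * fs / f0)
  sp <- (tr + 1):(length(a) - tr)
  stats::cor(a[sp], b[sp])
}

expect_between <- function(x, lo, hi) {
  expect_true(all(x >= lo & x <= hi),
              info = sprintf("value(s) outside [%g, %g]: %s", lo, hi,
                             paste(signif(x[x < lo | x > hi], 4),
                                   collapse = ", ")))
}
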