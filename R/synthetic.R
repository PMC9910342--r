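# Synthetic-signal generators with planted ground truth: glottal pulse trains
# with known OQ/SQ/ACFL, forward ACC synthesis through a known IBIF model,
# simulated laboratory calibration sessions (descending-loudness /p/-vowel
# strings with intraoral-pressure plateaus), and daylong ambulatory streams.
# Everything is deterministic under a fixed seed. These stand in for the human
# recordings, which are not publicly available; all generated artifacts are
# synthetic and labeled as such.

#' Specification of one simulated participant
#'
#' The planted Ps law is `Ps = slope * ACCrms + intercept + oq_coef *
#' (OQ - 60)`, in cm H2O with ACCrms in cm/s^2 and OQ in percent. Defaults
#' describe a modal adult speaker: laboratory Ps sweeps roughly 4--16 cm H2O
#' (laboratory elicitation typically tops out at 16--18 cm H2O), plateau noise
#' 0.3 cm H2O, 40 dB ACC SNR, loudest vowel near 92 dB SPL at 15 cm.
#'
#' @param sex `"male"` (foN 120 Hz, f0 base 115 Hz) or `"female"` (foN 190 Hz,
#'   f0 base 195 Hz).
#' @param ps_slope,ps_intercept,oq_coef planted Ps law coefficients.
#' @param ps_range laboratory Ps sweep range in cm H2O (soft to loud).
#' @param ibif_true the participant's true [ibif_params].
#' @param f0_base comfortable-pitch f0 in Hz (default by sex).
#' @param pitch_factors multiplicative f0 factors for the three pitch
#'   conditions.
#' @param oq_by_pitch mean OQ (%) per pitch condition.
#' @param sq_target speed quotient target (%).
#' @param n_trials,vowels,n_syllables elicitation protocol shape (at most 20
#'   vowel segments per breath-group string).
#' @param iop_sigma plateau noise SD in cm H2O (0 = noiseless).
#' @param acc_snr_db additive ACC noise level (Inf = noiseless).
#' @param aspiration_db aspiration-noise level relative to the voiced ACC RMS
#'   in dB (physiological turbulence; always present in real voice).
#' @param spl_max SPL of the loudest laboratory vowel, dB SPL at 15 cm.
#' @param spl_intercept planted ACC-to-SPL mapping intercept (slope 1).
#' @param seed RNG seed.
#' @return object of class `participant_spec`.
#' @export
participant_spec <- function(sex = c("male", "female"),
                             ps_slope = 0.5, ps_intercept = 2, oq_coef = 0,
                             ps_range = c(4, 16),
                             ibif_true = ibif_params(),
                             f0_base = NULL,
                             pitch_factors = c(comfortable = 1, higher = 1.25,
                                               lower = 0.85),
                             oq_by_pitch = c(comfortable = 60, higher = 55,
                                             lower = 65),
                             sq_target = 200,
                             n_trials = 2, vowels = c("a", "i", "u"),
                             n_syllables = 10,
                             iop_sigma = 0.3, acc_snr_db = 40,
                             aspiration_db = -35,
                             spl_max = 92, spl_intercept = 62,
                             seed = 1) {
  sex <- match.arg(sex)
  if (is.null(f0_base)) f0_base <- if (sex == "male") 115 else 195
  stopifnot(n_syllables >= 1, n_syllables <= 20, ps_range[1] < ps_range[2])
  structure(list(sex = sex, ps_slope = ps_slope, ps_intercept = ps_intercept,
                 oq_coef = oq_coef, ps_range = ps_range, ibif_true = ibif_true,
                 f0_base = f0_base, pitch_factors = pitch_factors,
                 oq_by_pitch = oq_by_pitch, sq_target = sq_target,
                 n_trials = n_trials, vowels = vowels,
                 n_syllables = n_syllables, iop_sigma = iop_sigma,
                 acc_snr_db = acc_snr_db, aspiration_db = aspiration_db,
                 spl_max = spl_max, spl_intercept = spl_intercept,
                 seed = seed),
            class = "participant_spec")
}

# Planted Ps law.
.ps_law <- function(spec, acc_rms, oq) {
  spec$ps_slope * acc_rms + spec$ps_intercept + spec$oq_coef * (oq - 60)
}

#' Glottal pulse train with planted time-domain features
#'
#' Piecewise pulses with a quarter-sine rise and quarter-cosine fall (maximum
#' negative slope at the closure instant, as in abrupt-closure glottal flow),
#' zero flow during the closed phase. The open phase ends each cycle, so the
#' closure instant coincides with the cycle boundary. Cycle lengths jitter by
#' `jitter` percent (Gaussian) when requested.
#'
#' @param f0 fundamental frequency in Hz.
#' @param oq_target open quotient target in percent (0 < OQ < 100).
#' @param sq_target speed quotient target in percent (> 0).
#' @param acfl_target peak-to-peak amplitude in mL/s.
#' @param duration length in seconds.
#' @param fs sampling rate in Hz.
#' @param jitter cycle-length jitter in percent of the period.
#' @param seed RNG seed (used only when `jitter > 0`).
#' @return list with `flow` (mL/s, baseline 0), `fs`, `f0`, and `gt`
#'   (data.frame of per-cycle ground truth: `start` 0-based sample, `period_s`,
#'   `oq`, `sq`).
#' @export
lf_pulse_train <- function(f0, oq_target = 60, sq_target = 200,
                           acfl_target = 300, duration = 0.2, fs = 20000,
                           jitter = 0, seed = 1) {
  if (oq_target <= 0 || oq_target >= 100) stop("oq_target must be in (0, 100)")
  if (sq_target <= 0) stop("sq_target must be positive")
  n <- as.integer(round(duration * fs))
  periods <- with_seed(seed, {
    t0 <- 1 / f0
    ps <- numeric(0)
    total <- 0
    while (total < duration + t0) {
      p <- t0 * (1 + if (jitter > 0) stats::rnorm(1, 0, jitter / 100) else 0)
      p <- max(p, 0.3 * t0)
      ps <- c(ps, p)
      total <- total + p
    }
    ps
  })
  flow <- numeric(n)
  gt <- list()
  pos <- 0
  for (ci in seq_along(periods)) {
    p <- periods[ci]
    np <- as.integer(round(p * fs))
    if (pos + np > n) break
    t_o <- oq_target / 100 * np
    t_op <- t_o * sq_target / (100 + sq_target)
    t_cp <- t_o - t_op
    # open phase occupies the end of the cycle; closure at the cycle boundary
    i <- seq_len(np) - 1L
    open_start <- np - t_o
    pulse <- numeric(np)
    rise <- i >= open_start & i < open_start + t_op
    fall <- i >= open_start + t_op & i < np
    pulse[rise] <- sin(pi / 2 * (i[rise] - open_start) / t_op)
    pulse[fall] <- cos(pi / 2 * (i[fall] - open_start - t_op) / t_cp)
    flow[(pos + 1L):(pos + np)] <- acfl_target * pulse
    gt[[ci]] <- data.frame(start = pos, period_s = np / fs,
                           oq = 100 * t_o / np, sq = 100 * t_op / t_cp)
    pos <- pos + np
  }
  list(flow = flow, fs = fs, f0 = f0, gt = do.call(rbind, gt))
}

# High-passed aspiration noise at `level_db` relative to rms(x).
.aspiration <- function(x, fs, level_db) {
  if (!is.finite(level_db)) return(x)
  noise <- stats::rnorm(length(x))
  noise <- fft_bandpass(noise, fs, f_lo = 1500, f_hi = 0.45 * fs)
  target <- frame_rms(x) * 10^(level_db / 20)
  x + noise / max(frame_rms(noise), 1e-12) * target
}

# Two-formant vowel resonator applied to the flow derivative (recursive
# two-pole sections): enough structure for energy-based segmentation and SPL.
.vowel_formants <- list(a = c(700, 1200), i = c(300, 2300), u = c(350, 800))

.formant_filter <- function(x, fs, vowel) {
  fmts <- .vowel_formants[[vowel]]
  if (is.null(fmts)) fmts <- .vowel_formants$a
  y <- c(0, diff(x)) # radiation-ish derivative
  for (fc in fmts) {
    bw <- 0.1 * fc + 50
    r <- exp(-pi * bw / fs)
    th <- 2 * pi * fc / fs
    a1 <- 2 * r * cos(th)
    a2 <- -r^2
    y <- stats::filter(y * (1 - r), c(a1, a2), method = "recursive")
  }
  as.numeric(y)
}

#' Simulate a laboratory calibration session
#'
#' Descending-loudness /p/-vowel syllable strings across the requested trials,
#' vowels and pitch conditions, at the laboratory rate of 20 kHz. Each vowel is
#' bracketed by trapezoidal intraoral-pressure plateaus (80-ms flat top) whose
#' peaks are planted so that the mean of the two bracketing peaks equals the
#' true Ps; the ACC channel is the glottal flow forward-filtered through the
#' participant's true IBIF model and scaled so that the middle-50-ms RMS
#' matches the value implied by the planted Ps law; the microphone channel is
#' a two-formant rendering of the flow derivative scaled so the loudest vowel
#' reaches `spl_max`.
#'
#' @param spec a [participant_spec].
#' @param fs laboratory sampling rate in Hz.
#' @param emit_raw_acc also emit the raw 11,025-Hz delayed ACC stream
#'   (`acc_raw`), for exercising the resample-and-align pre-processing path.
#' @param acc_delay_s acquisition delay planted in `acc_raw`, seconds.
#' @return list with [calibrated_signal]s `mic`, `flow`, `iop`, `acc` (20 kHz,
#'   aligned), optionally `acc_raw` (11,025 Hz, delayed), `truth` (data.frame
#'   per vowel segment: `trial`, `vowel`, `pitch`, `start`, `end` 0-based at
#'   `fs`, `ps_true`, `f0_true`, `oq_true`, `sq_true`, `acc_rms_true`),
#'   `spl_mapping_true`, and `spec`.
#' @export
synthesize_lab_session <- function(spec, fs = 20000, emit_raw_acc = FALSE,
                                   acc_delay_s = 0.0125) {
  stopifnot(inherits(spec, "participant_spec"))
  with_seed(spec$seed, .synthesize_lab_session(spec, fs, emit_raw_acc,
                                               acc_delay_s))
}

.synthesize_lab_session <- function(spec, fs, emit_raw_acc, acc_delay_s) {
  vdur <- 0.22; gap <- 0.14; lead <- 0.35
  nv <- spec$n_syllables
  pitches <- names(spec$pitch_factors)
  mic <- flow <- iop <- acc <- numeric(0)
  truth <- list(); ti <- 0L
  mic_segments <- list()
  for (trial in seq_len(spec$n_trials)) for (vw in spec$vowels)
    for (pc in pitches) {
      f0 <- spec$f0_base * spec$pitch_factors[[pc]]
      oq_mu <- spec$oq_by_pitch[[pc]]
      # descending Ps, loud -> soft, with mild per-syllable variation
      ps_seq <- seq(spec$ps_range[2], spec$ps_range[1], length.out = nv) +
        stats::rnorm(nv, 0, 0.1 * (nv > 1))
      oq_seq <- pmin(95, pmax(30, oq_mu + stats::runif(nv, -5, 5)))
      # bracketing plateau heights: mean(p_k, p_k+1) = ps_true_k
      pk <- numeric(nv + 1L)
      pk[1] <- ps_seq[1]
      for (k in seq_len(nv)) pk[k + 1L] <- 2 * ps_seq[k] - pk[k]
      pk <- pmax(pk, 0.5)
      ps_true <- (pk[-length(pk)] + pk[-1]) / 2
      smic <- sflow <- siop <- sacc <- rep(0, as.integer(round(lead * fs)))
      for (k in seq_len(nv)) {
        # plateau k in the gap before vowel k
        g <- .iop_plateau(pk[k], gap, fs, spec$iop_sigma)
        zg <- rep(0, length(g))
        smic <- c(smic, zg); sflow <- c(sflow, zg); sacc <- c(sacc, zg)
        siop <- c(siop, g)
        # vowel k
        f0k <- f0 * (1 + stats::rnorm(1, 0, 0.01))
        tr <- lf_pulse_train(f0k, oq_seq[k], spec$sq_target, acfl_target = 1,
                             duration = vdur, fs = fs, jitter = 0.3,
                             seed = stats::runif(1, 1, 2^30))
        u <- tr$flow * .edge_taper(length(tr$flow), fs)
        a <- forward_ibif(u, fs, spec$ibif_true)
        seg0 <- length(sacc)
        w <- segment_mid_window(seg0, seg0 + length(a), fs)
        rms0 <- frame_rms(a[(w$start - seg0 + 1L):(w$end - seg0)])
        acc_rms_target <- (ps_true[k] - spec$ps_intercept -
                             spec$oq_coef * (oq_seq[k] - 60)) / spec$ps_slope
        if (acc_rms_target <= 0) acc_rms_target <- 0.05
        sc <- acc_rms_target / max(rms0, 1e-12)
        u <- u * sc; a <- a * sc
        a <- .aspiration(a, fs, spec$aspiration_db)
        m <- .formant_filter(u, fs, vw)
        ti <- ti + 1L
        truth[[ti]] <- data.frame(trial = trial, vowel = vw, pitch = pc,
                                  start = NA_integer_, end = NA_integer_,
                                  seg_offset = seg0,
                                  ps_true = ps_true[k], f0_true = f0k,
                                  oq_true = oq_seq[k], sq_true = spec$sq_target,
                                  acc_rms_true = acc_rms_target)
        mic_segments[[ti]] <- list(len = length(a))
        smic <- c(smic, m); sflow <- c(sflow, u + 80); sacc <- c(sacc, a)
        siop <- c(siop, rep(0, length(a)))
      }
      # trailing plateau after the last vowel
      g <- .iop_plateau(pk[nv + 1L], gap, fs, spec$iop_sigma)
      zg <- rep(0, length(g))
      smic <- c(smic, zg); sflow <- c(sflow, zg); sacc <- c(sacc, zg)
      siop <- c(siop, g)
      # fix up absolute segment bounds for this string
      base <- length(acc)
      for (j in (ti - nv + 1L):ti) {
        truth[[j]]$start <- base + truth[[j]]$seg_offset
        truth[[j]]$end <- base + truth[[j]]$seg_offset + mic_segments[[j]]$len
      }
      mic <- c(mic, smic); flow <- c(flow, sflow)
      iop <- c(iop, siop); acc <- c(acc, sacc)
    }
  tail_z <- rep(0, as.integer(round(0.35 * fs)))
  mic <- c(mic, tail_z); flow <- c(flow, tail_z)
  iop <- c(iop, tail_z); acc <- c(acc, tail_z)
  truth <- do.call(rbind, truth)
  truth$seg_offset <- NULL
  # scale microphone so the loudest vowel hits spl_max
  spl_now <- -Inf
  for (j in seq_len(nrow(truth))) {
    w <- segment_mid_window(truth$start[j], truth$end[j], fs)
    r <- frame_rms(mic[(w$start + 1L):w$end])
    if (r > 0) spl_now <- max(spl_now, 20 * log10(r / 20e-6))
  }
  mic <- mic * 10^((spec$spl_max - spl_now) / 20)
  if (is.finite(spec$acc_snr_db)) {
    acc_noise <- stats::rnorm(length(acc))
    vo <- acc[abs(acc) > 0]
    sig_rms <- if (length(vo)) sqrt(mean(vo^2)) else 1
    acc <- acc + acc_noise * sig_rms * 10^(-spec$acc_snr_db / 20)
  }
  out <- list(mic = calibrated_signal(mic, fs, "MIC"),
              flow = calibrated_signal(flow, fs, "FLOW"),
              iop = calibrated_signal(iop, fs, "IOP"),
              acc = calibrated_signal(acc, fs, "ACC"),
              truth = truth,
              spl_mapping_true = structure(
                list(slope = 1, intercept = spec$spl_intercept,
                     n = NA_integer_, span_db = NA_real_, reliable = TRUE),
                class = "spl_mapping"),
              spec = spec)
  if (emit_raw_acc) {
    raw <- resample_core(acc, fs, 11025)
    raw <- c(rep(0, as.integer(round(acc_delay_s * 11025))), raw)
    out$acc_raw <- calibrated_signal(raw, 11025, "ACC")
    out$acc_delay_s <- acc_delay_s
  }
  out
}

# Trapezoidal intraoral-pressure pulse filling a gap of `dur` seconds:
# 20-ms ramps, 80-ms flat top at `height`. Plateau noise is a slow breath-
# pressure wobble: a single Gaussian offset per plateau (SD `sigma`) plus a
# small smooth ripple, so the sample-max peak is `height + N(0, sigma)` rather
# than being biased upward as per-sample white noise would be.
.iop_plateau <- function(height, dur, fs, sigma) {
  n <- as.integer(round(dur * fs))
  ramp <- as.integer(round(0.02 * fs))
  top <- as.integer(round(0.08 * fs))
  pad <- max(0L, (n - 2L * ramp - top) %/% 2L)
  top <- n - 2L * ramp - 2L * pad
  u <- c(rep(0, pad), seq(0, 1, length.out = ramp),
         rep(1, top), seq(1, 0, length.out = ramp), rep(0, n))[seq_len(n)]
  h <- height
  y <- u * h
  if (sigma > 0) {
    h <- max(height + stats::rnorm(1, 0, sigma), 0.1)
    ripple <- fft_bandpass(stats::rnorm(n), fs, f_hi = 15)
    ripple <- ripple / max(abs(ripple), 1e-12) * sigma / 10
    y <- u * h + (u > 0.5) * ripple
  }
  pmax(y, 0)
}

.edge_taper <- function(n, fs, ramp_s = 0.01) {
  r <- min(as.integer(round(ramp_s * fs)), n %/% 2L)
  w <- rep(1, n)
  if (r > 1L) {
    up <- 0.5 - 0.5 * cos(pi * (seq_len(r) - 1L) / (r - 1L))
    w[seq_len(r)] <- up
    w[(n - r + 1L):n] <- rev(up)
  }
  w
}

#' Simulate a daylong ambulatory accelerometer stream
#'
#' Alternating voiced and unvoiced spans at 11,025 Hz, aligned to the 50-ms
#' frame grid. Voiced spans carry glottal-pulse-driven ACC with slow loudness
#' (+/- `loud_drift_db` dB) and pitch (+/- `f0_drift` fractional) drift plus a
#' random walk; per-frame gains are set exactly so the planted Ps law holds
#' frame by frame. Unvoiced spans are low-level broadband noise below the
#' voice-activity SPL criterion.
#'
#' @param spec a [participant_spec].
#' @param duration_h stream duration in hours.
#' @param voiced_fraction target fraction of voiced frames.
#' @param loud_drift_db,f0_drift drift depths.
#' @param fs ambulatory sampling rate in Hz.
#' @return list with `acc` ([calibrated_signal]), `truth` (per-frame
#'   data.frame: `frame`, `t_start`, `voiced`, `ps_true`, `f0_true`,
#'   `rms_true`), `spl_mapping_true`, `spec`.
#' @export
synthesize_day <- function(spec, duration_h = 0.5, voiced_fraction = 0.3,
                           loud_drift_db = 8, f0_drift = 0.2, fs = 11025) {
  stopifnot(inherits(spec, "participant_spec"),
            voiced_fraction >= 0, voiced_fraction <= 1)
  with_seed(spec$seed + 104729L, {
    frame_len <- as.integer(round(0.05 * fs))
    n_frames <- as.integer(round(duration_h * 3600 / 0.05))
    n <- n_frames * frame_len
    x <- numeric(n)
    voiced <- logical(n_frames)
    ps_true <- rep(NA_real_, n_frames)
    f0_true <- rep(NA_real_, n_frames)
    rms_true <- rep(NA_real_, n_frames)
    # plan voiced runs on the frame grid
    fr <- 1L
    vf <- max(voiced_fraction, 1e-9)
    while (fr <= n_frames) {
      vlen <- sample(10:40, 1)                       # 0.5--2 s voiced
      slen <- max(1, min(round(vlen * (1 - vf) / vf *
                                 stats::runif(1, 0.6, 1.4)),
                         n_frames + 1))
      if (voiced_fraction == 0) vlen <- 0L
      if (vlen > 0L && fr + vlen - 1L <= n_frames) {
        voiced[fr:(fr + vlen - 1L)] <- TRUE
      } else if (vlen > 0L) {
        voiced[fr:n_frames] <- TRUE
      }
      fr <- fr + vlen + slen
    }
    # drift contours on the frame grid
    t_fr <- (seq_len(n_frames) - 1L) * 0.05
    rw1 <- cumsum(stats::rnorm(n_frames, 0, 0.05)); rw1 <- rw1 - mean(rw1)
    rw2 <- cumsum(stats::rnorm(n_frames, 0, 0.002)); rw2 <- rw2 - mean(rw2)
    mid_rms_db <- 20 * log10(mean(spec$ps_range) / spec$ps_slope)
    rms_db <- mid_rms_db + loud_drift_db * sin(2 * pi * t_fr / 900) +
      pmin(pmax(rw1, -4), 4)
    f0_c <- spec$f0_base * (1 + f0_drift * sin(2 * pi * t_fr / 600) +
                              pmin(pmax(rw2, -0.1), 0.1))
    oq_day <- spec$oq_by_pitch[["comfortable"]]
    r <- rle(voiced)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      fr0 <- starts[k]; fr1 <- ends[k]
      s0 <- (fr0 - 1L) * frame_len + 1L
      s1 <- fr1 * frame_len
      if (!r$values[k]) {
        # unvoiced: broadband noise around 35 dB SPL under the planted mapping
        rms_uv <- 10^((35 - spec$spl_intercept) / 20)
        x[s0:s1] <- stats::rnorm(s1 - s0 + 1L, 0, rms_uv)
        next
      }
      f0s <- stats::median(f0_c[fr0:fr1])
      tr <- lf_pulse_train(f0s, oq_day, spec$sq_target, acfl_target = 1,
                           duration = (s1 - s0 + 1L) / fs, fs = fs,
                           jitter = 0.3, seed = stats::runif(1, 1, 2^30))
      u <- tr$flow[seq_len(s1 - s0 + 1L)]
      a <- forward_ibif(u * .edge_taper(length(u), fs, 0.005), fs,
                        spec$ibif_true)
      a <- .aspiration(a, fs, spec$aspiration_db)
      # per-frame gain so the frame RMS equals the planted target exactly
      for (f in fr0:fr1) {
        i0 <- (f - fr0) * frame_len + 1L
        i1 <- i0 + frame_len - 1L
        tgt <- 10^(rms_db[f] / 20)
        r0 <- frame_rms(a[i0:i1])
        gain <- tgt / max(r0, 1e-12)
        a[i0:i1] <- a[i0:i1] * gain
        ps_true[f] <- .ps_law(spec, tgt, oq_day)
        f0_true[f] <- f0s
        rms_true[f] <- tgt
      }
      x[s0:s1] <- a
    }
    if (is.finite(spec$acc_snr_db)) {
      vo <- which(voiced)
      sig_rms <- if (length(vo)) stats::median(rms_true[vo]) else 1
      x <- x + stats::rnorm(n, 0, sig_rms * 10^(-spec$acc_snr_db / 20))
    }
    list(acc = calibrated_signal(x, fs, "ACC"),
         truth = data.frame(frame = seq_len(n_frames) - 1L,
                            t_start = t_fr, voiced = voiced,
                            ps_true = ps_true, f0_true = f0_true,
                            rms_true = rms_true),
         spl_mapping_true = structure(
           list(slope = 1, intercept = spec$spl_intercept,
                n = NA_integer_, span_db = NA_real_, reliable = TRUE),
           class = "spl_mapping"),
         spec = spec)
  })
}

#' Segment-level Method 2 simulator
#'
#' Draws ACC RMS values uniformly over `acc_range` and plants
#' `Ps = slope * ACCrms + intercept + N(0, sigma)`. Used for statistical
#' recovery checks where full signal synthesis is unnecessary.
#'
#' @param n number of segments.
#' @param slope,intercept planted line.
#' @param sigma Ps noise SD in cm H2O.
#' @param acc_range ACC RMS range in cm/s^2.
#' @param seed RNG seed.
#' @return data.frame with `acc_rms`, `ps_ref`.
#' @export
simulate_method2_data <- function(n = 60, slope = 2, intercept = 3,
                                  sigma = 0.5, acc_range = c(0.5, 6.5),
                                  seed = 1) {
  with_seed(seed, {
    acc <- stats::runif(n, acc_range[1], acc_range[2])
    data.frame(acc_rms = acc,
               ps_ref = slope * acc + intercept + stats::rnorm(n, 0, sigma))
  })
}

#' Segment-level feature-table simulator for Method 3
#'
#' Generates the ten vocal-function measures at physiologically plausible
#' scales, mutually independent, and plants a linear Ps law over the named
#' coefficients plus Gaussian noise. Non-named measures act as decoys.
#'
#' @param n segments.
#' @param coefs named numeric vector of planted coefficients (names from the
#'   canonical measure set); empty means all-noise features.
#' @param intercept planted intercept in cm H2O.
#' @param sigma noise SD in cm H2O.
#' @param seed RNG seed.
#' @return list with `features` (data.frame, ten columns), `ps_ref`, `coefs`.
#' @export
simulate_feature_table <- function(n = 60, coefs = c(rms = 2),
                                   intercept = 3, sigma = 0.5, seed = 1) {
  scales <- list(rms = c(3, 2), f0 = c(150, 30), cpp = c(20, 4),
                 acfl = c(250, 80), mfdr = c(300, 100), oq = c(60, 8),
                 sq = c(180, 40), h1h2 = c(6, 4), hrf = c(-4, 3),
                 naq = c(0.18, 0.05))
  with_seed(seed, {
    features <- as.data.frame(lapply(scales, function(s)
      stats::rnorm(n, s[1], s[2])))
    ps <- rep(intercept, n)
    for (nm in names(coefs)) ps <- ps + coefs[[nm]] * features[[nm]]
    ps <- ps + stats::rnorm(n, 0, sigma)
    list(features = features, ps_ref = ps, coefs = coefs)
  })
}
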