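# Frame-level scalar features from accelerometer and microphone windows: RMS,
# SPL re 20 uPa at 15 cm, fundamental frequency by normalized autocorrelation
# with subharmonic (octave-error) correction, cepstral peak prominence, the
# low-to-high spectral power ratio, and the log-log ACC-to-SPL mapping used
# when no microphone is available.

#' Root-mean-square of a window
#' @param x numeric window (non-empty).
#' @return `sqrt(mean(x^2))` in window units.
#' @export
frame_rms <- function(x) {
  stopifnot(length(x) > 0L)
  sqrt(mean(x^2))
}

#' Sound pressure level of a microphone window
#'
#' `20 * log10(MICrms / 20 uPa)` where MICrms is the RMS of the window (the
#' middle 50 ms of the vowel in laboratory use), referenced to a 15-cm
#' mouth-to-microphone distance.
#'
#' @param mic_window numeric window in Pa.
#' @return dB SPL at 15 cm.
#' @export
spl_from_mic <- function(mic_window) {
  r <- frame_rms(mic_window)
  if (r <= 0) stop("undefined SPL: zero-energy window")
  20 * log10(r / 20e-6)
}

#' Fundamental frequency by normalized autocorrelation with octave correction
#'
#' The f0 is the reciprocal of the first peak location in the normalized
#' autocorrelation within `[1/fmax, 1/fmin]` (parabolic interpolation). If a
#' secondary peak near double that lag has amplitude at least
#' `subharmonic_threshold` times the first peak, the f0 is recomputed from the
#' subharmonic lag: a boosted second harmonic (e.g. from the subglottal
#' resonance) otherwise halves the period. When no distinct subharmonic peak
#' exists, `subharmonic_peak` is reported as the main peak amplitude.
#'
#' @param window numeric window (at least two periods at `fmin`).
#' @param fs sampling rate in Hz.
#' @param fmin,fmax f0 search range in Hz.
#' @param subharmonic_threshold relative amplitude triggering recomputation.
#' @param peak_floor minimum normalized peak amplitude to call the frame
#'   voiced.
#' @return list with `f0` (Hz, `NA` when unvoiced), `autocorr_peak`,
#'   `subharmonic_peak`, `voiced`.
#' @export
f0_autocorrelation <- function(window, fs, fmin = 70, fmax = 1000,
                               subharmonic_threshold = 0.25, peak_floor = 0.3) {
  stopifnot(fmin < fmax)
  n <- length(window)
  unvoiced <- list(f0 = NA_real_, autocorr_peak = 0, subharmonic_peak = 0,
                   voiced = FALSE)
  if (n < 4L || stats::sd(window) == 0) return(unvoiced)
  r <- autocorr_norm(window)
  lmin <- max(2L, as.integer(floor(fs / fmax)))
  lmax <- min(n - 2L, as.integer(ceiling(fs / fmin)))
  if (lmax <= lmin + 1L) return(unvoiced)
  # Highest local maximum above the floor in the lag band (r index = lag+1).
  # The biased autocorrelation estimate decays with lag, so for a signal of
  # period T the T peak dominates its 2T, 3T replicas, while spurious
  # sub-period peaks (strong upper harmonics) stay below it; taking the
  # highest peak rather than the literal first avoids harmonic-lag errors.
  idx <- (lmin + 1L):(lmax + 1L)
  is_peak <- r[idx] >= peak_floor & r[idx] >= r[idx - 1L] & r[idx] > r[idx + 1L]
  if (!any(is_peak)) return(unvoiced)
  peaks <- idx[is_peak]
  # among near-equal peaks (within 5% of the best) take the shortest lag, so
  # the period-T peak beats its own 2T, 3T replicas
  peak_i <- peaks[r[peaks] >= 0.95 * max(r[peaks])][1]
  p1 <- .parabolic_peak(r, peak_i)
  lag1 <- p1$pos - 1
  amp1 <- min(p1$val, 1)
  f0 <- fs / lag1
  sub_amp <- amp1
  # Subharmonic candidate at ~double the lag (octave-down correction). Any
  # periodic signal has a replica peak near 2x the lag, so firing on the
  # 0.25 threshold alone would halve every f0; the correction additionally
  # requires the double-lag peak to be at least comparable (>= 90%) to the
  # chosen peak -- the signature of a boosted second harmonic having pulled
  # the main peak to the half period.
  lo <- as.integer(floor(2 * lag1 * 0.9))
  hi <- as.integer(ceiling(2 * lag1 * 1.1))
  if (hi <= n - 2L) {
    band <- (lo + 1L):(hi + 1L)
    j <- band[which.max(r[band])]
    if (j > 1L && j < n) {
      p2 <- .parabolic_peak(r, j)
      sub_amp <- min(max(p2$val, 0), 1)
      if (sub_amp >= subharmonic_threshold * amp1 && sub_amp > amp1) {
        f0 <- fs / (p2$pos - 1)
      }
    }
  }
  list(f0 = f0, autocorr_peak = amp1, subharmonic_peak = sub_amp, voiced = TRUE)
}

#' Cepstral peak prominence
#'
#' Hann-windowed dB-magnitude spectrum (FFT zero-padded to at least 8192),
#' real cepstrum, and the difference in dB between the cepstral peak in the
#' quefrency band `[qmin, qmax]` and a linear regression line fit to the
#' cepstrum over that band, evaluated at the peak quefrency. Invariant to
#' overall gain (a gain shift only moves the zero-quefrency bin).
#'
#' @param window numeric window, at least 50 ms long.
#' @param fs sampling rate in Hz.
#' @param qmin,qmax quefrency band in seconds (defaults 1/500 to 1/70 s,
#'   matching the 70--500 Hz usable f0 range of glottal analysis).
#' @return CPP in dB.
#' @export
cpp <- function(window, fs, qmin = 1 / 500, qmax = 1 / 70) {
  n <- length(window)
  if (n < round(0.05 * fs)) stop("cpp window must be at least 50 ms")
  w <- window * hann_window(n)
  nfft <- max(8192L, next_pow2(n))
  S <- 20 * log10(Mod(stats::fft(c(w, rep(0, nfft - n)))) + 1e-300)
  Cq <- Mod(stats::fft(S, inverse = TRUE) / nfft)
  qf <- (seq_len(nfft) - 1L) / fs
  band <- which(qf >= qmin & qf <= qmax)
  if (length(band) < 8L) stop("quefrency band too narrow for this fs")
  cdb <- 20 * log10(Cq[band] + 1e-300)
  q <- qf[band]
  fit <- stats::lm.fit(cbind(1, q), cdb)
  i <- which.max(cdb)
  cdb[i] - (fit$coefficients[1] + fit$coefficients[2] * q[i])
}

#' Low-to-high spectral power ratio
#'
#' `10 * log10` of the ratio of spectral power below to above `split` Hz
#' (default 2000 Hz), computed on the Hann-windowed frame. Part of the
#' five-feature voice-activity detector.
#'
#' @param window numeric frame.
#' @param fs sampling rate in Hz.
#' @param split split frequency in Hz.
#' @return ratio in dB.
#' @export
lh_ratio <- function(window, fs, split = 2000) {
  n <- length(window)
  w <- (window - mean(window)) * hann_window(n)
  nfft <- next_pow2(n)
  P <- Mod(stats::fft(c(w, rep(0, nfft - n))))^2
  P <- P[seq_len(nfft %/% 2L + 1L)]
  f <- (seq_along(P) - 1L) * fs / nfft
  lo <- sum(P[f <= split & f > 0])
  hi <- sum(P[f > split])
  10 * log10((lo + 1e-300) / (hi + 1e-300))
}

#' Fit the log-log ACC-to-SPL mapping
#'
#' Ordinary least squares in (dB, dB) space between the accelerometer level
#' (`20 * log10(ACCrms)` re 1 cm/s^2) and the microphone SPL, from the
#' descending-loudness /a/ calibration at the start of the monitored day.
#'
#' @param acc_rms_db accelerometer level per frame, dB re 1 cm/s^2.
#' @param spl matching SPL per frame, dB SPL at 15 cm.
#' @return object of class `spl_mapping` with `slope`, `intercept`, `n`,
#'   `span_db` and `reliable` (FALSE when the SPL span is below 10 dB).
#' @export
fit_spl_mapping <- function(acc_rms_db, spl) {
  stopifnot(length(acc_rms_db) == length(spl))
  if (length(spl) < 5L) stop("spl mapping requires at least 5 paired frames")
  span <- diff(range(spl))
  if (stats::sd(acc_rms_db) == 0) stop("degenerate fit: constant ACC level")
  fit <- stats::lm.fit(cbind(1, acc_rms_db), spl)
  m <- structure(list(slope = unname(fit$coefficients[2]),
                      intercept = unname(fit$coefficients[1]),
                      n = length(spl), span_db = span,
                      reliable = span >= 10),
                 class = "spl_mapping")
  if (!m$reliable) warning("unreliable SPL mapping: span below 10 dB")
  m
}

#' Map accelerometer RMS to SPL
#'
#' @param mapping an `spl_mapping` from [fit_spl_mapping()].
#' @param acc_rms accelerometer RMS in cm/s^2 (linear units).
#' @return dB SPL at 15 cm.
#' @export
acc_to_spl <- function(mapping, acc_rms) {
  stopifnot(inherits(mapping, "spl_mapping"))
  mapping$slope * 20 * log10(pmax(acc_rms, 1e-12)) + mapping$intercept
}

#' All frame features needed by the voice-activity detector
#'
#' @param window accelerometer frame in cm/s^2.
#' @param fs sampling rate in Hz.
#' @param spl_mapping `spl_mapping` used to derive SPL from the ACC level.
#' @param fmin,fmax f0 search range in Hz.
#' @param compute_cpp whether to compute CPP (needs a 50-ms window).
#' @return one-row data.frame with `rms`, `spl`, `f0`, `autocorr_peak`,
#'   `subharmonic_peak`, `lh_ratio`, `cpp`.
#' @export
frame_features <- function(window, fs, spl_mapping, fmin = 70, fmax = 1000,
                           compute_cpp = TRUE) {
  rms <- frame_rms(window)
  spl <- acc_to_spl(spl_mapping, rms)
  p <- f0_autocorrelation(window, fs, fmin = fmin, fmax = fmax)
  lh <- lh_ratio(window, fs)
  cp <- if (compute_cpp && length(window) >= round(0.05 * fs)) cpp(window, fs)
        else NA_real_
  data.frame(rms = rms, spl = spl, f0 = p$f0,
             autocorr_peak = p$autocorr_peak,
             subharmonic_peak = p$subharmonic_peak,
             lh_ratio = lh, cpp = cp)
}
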