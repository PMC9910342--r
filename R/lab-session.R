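# Segmentation of the laboratory calibration recording: vowel segments from
# the microphone energy contour, intraoral-pressure plateaus between them, and
# the reference subglottal pressure per vowel (mean of the bracketing plateau
# peaks). Sample indexing is 0-based with half-open intervals [start, end).

#' Detect vowel segments from the microphone energy contour
#'
#' A 10-ms RMS energy contour is computed on the microphone signal; a segment
#' is a maximal run of frames whose energy exceeds the noise floor by
#' `energy_threshold_db` for at least `min_duration` seconds. Segments shorter
#' than 60 ms are kept but flagged (`flag_short`): they cannot host the
#' middle-50-ms feature window.
#'
#' @param mic a [calibrated_signal] (MIC channel).
#' @param min_duration minimum segment duration in seconds.
#' @param energy_threshold_db threshold above the noise floor in dB.
#' @param frame_s energy frame length in seconds.
#' @return data.frame with 0-based `start`, `end` (half-open, samples),
#'   `start_s`, `end_s`, `flag_short`.
#' @export
segment_vowels <- function(mic, min_duration = 0.08, energy_threshold_db = 20,
                           frame_s = 0.01) {
  x <- mic$samples
  fs <- mic$fs
  hop <- max(1L, as.integer(round(frame_s * fs)))
  nfr <- length(x) %/% hop
  empty <- data.frame(start = integer(0), end = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      flag_short = logical(0))
  if (nfr < 2L) return(empty)
  m <- matrix(x[seq_len(nfr * hop)], nrow = hop)
  e_db <- 10 * log10(colMeans(m^2) + 1e-300)
  floor_db <- stats::quantile(e_db, 0.10, names = FALSE)
  thr <- floor_db + energy_threshold_db
  above <- e_db > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * hop / fs >= min_duration)
  if (!any(keep)) return(empty)
  s <- (starts[keep] - 1L) * hop
  e <- ends[keep] * hop
  data.frame(start = s, end = e, start_s = s / fs, end_s = e / fs,
             flag_short = (e - s) / fs < 0.06)
}

#' Detect intraoral-pressure plateaus between vowel segments
#'
#' One plateau is reported per inter-vowel gap (including the gaps before the
#' first and after the last vowel) whose maximum exceeds `min_height`. The
#' plateau peak is the maximum IOP sample within the gap; a flatness metric
#' (max - min over the 20 ms around the peak) is recorded for QC only.
#'
#' @param iop a [calibrated_signal] (IOP channel, cm H2O).
#' @param vowels data.frame from [segment_vowels()] (sorted, non-overlapping).
#' @param min_height minimum peak amplitude in cm H2O to call a plateau.
#' @return data.frame with `peak_time` (0-based sample), `peak_amplitude`
#'   (cm H2O), `gap_index`, `flatness`.
#' @export
detect_iop_plateaus <- function(iop, vowels, min_height = 1) {
  x <- iop$samples
  fs <- iop$fs
  n <- length(x)
  bounds <- c(0L, as.integer(rbind(vowels$start, vowels$end)), n)
  # gaps are [bounds[2k+1], bounds[2k+2]) for k = 0..nrow(vowels)
  out <- list()
  gi <- 0L
  for (k in seq_len(nrow(vowels) + 1L)) {
    g0 <- bounds[2L * k - 1L]
    g1 <- bounds[2L * k]
    if (g1 - g0 < round(0.01 * fs)) next
    seg <- x[(g0 + 1L):g1]
    # one plateau per contiguous supra-threshold run: the gap between two
    # breath-group strings legitimately contains the trailing plateau of one
    # string and the leading plateau of the next
    r <- rle(seg >= min_height)
    rends <- cumsum(r$lengths)
    rstarts <- rends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= round(0.01 * fs))) {
      sub <- seg[rstarts[j]:rends[j]]
      mx <- max(sub)
      pk <- g0 + rstarts[j] + which.max(sub) - 2L
      w0 <- max(g0, pk - round(0.01 * fs))
      w1 <- min(g1 - 1L, pk + round(0.01 * fs))
      win <- x[(w0 + 1L):(w1 + 1L)]
      gi <- gi + 1L
      out[[gi]] <- data.frame(peak_time = pk, peak_amplitude = mx,
                              gap_index = k - 1L,
                              flatness = max(win) - min(win))
    }
  }
  if (gi == 0L) {
    return(data.frame(peak_time = integer(0), peak_amplitude = numeric(0),
                      gap_index = integer(0), flatness = numeric(0)))
  }
  do.call(rbind, out)
}

#' Reference subglottal pressure for one vowel segment
#'
#' The reference Ps is the mean of the peak amplitudes of the intraoral
#' pressure plateaus immediately preceding and following the vowel. When only
#' one adjacent plateau exists the single peak is returned but flagged
#' (`"single_plateau"`); such segments are excluded from model fitting.
#'
#' @param segment one-row data.frame (or list) with `start` and `end`.
#' @param plateaus data.frame from [detect_iop_plateaus()].
#' @return list with `ps_ref` (cm H2O), `n_adjacent`, `flag`.
#' @export
reference_ps <- function(segment, plateaus) {
  pre <- plateaus[plateaus$peak_time < segment$start, , drop = FALSE]
  post <- plateaus[plateaus$peak_time >= segment$end, , drop = FALSE]
  p_pre <- if (nrow(pre)) pre$peak_amplitude[which.max(pre$peak_time)] else NA_real_
  p_post <- if (nrow(post)) post$peak_amplitude[which.min(post$peak_time)] else NA_real_
  n_adj <- sum(!is.na(c(p_pre, p_post)))
  if (n_adj == 0L) stop("missing reference: no adjacent intraoral pressure plateau")
  if (n_adj == 1L) {
    return(list(ps_ref = if (is.na(p_pre)) p_post else p_pre,
                n_adjacent = 1L, flag = "single_plateau"))
  }
  list(ps_ref = (p_pre + p_post) / 2, n_adjacent = 2L, flag = "ok")
}

#' Reference Ps for every segment of a session
#'
#' @param vowels data.frame of vowel segments.
#' @param plateaus data.frame of IOP plateaus.
#' @return `vowels` with added `ps_ref` and `ps_flag` columns (`NA`/
#'   `"missing"` when no adjacent plateau exists).
#' @export
reference_ps_table <- function(vowels, plateaus) {
  vowels$ps_ref <- NA_real_
  vowels$ps_flag <- "missing"
  for (i in seq_len(nrow(vowels))) {
    r <- tryCatch(reference_ps(vowels[i, ], plateaus), error = function(e) NULL)
    if (!is.null(r)) {
      vowels$ps_ref[i] <- r$ps_ref
      vowels$ps_flag[i] <- r$flag
    }
  }
  vowels
}

#' Extract the middle 50-ms window of a segment
#'
#' Shared by the feature extractors and the synthetic generator so that
#' closed-loop checks measure exactly the window the generator planted.
#'
#' @param start,end 0-based half-open segment bounds in samples.
#' @param fs sampling rate in Hz.
#' @param width_s window width in seconds.
#' @return list with 0-based half-open `start`, `end` of the window.
#' @export
segment_mid_window <- function(start, end, fs, width_s = 0.05) {
  w <- as.integer(round(width_s * fs))
  mid <- as.integer((start + end) %/% 2L)
  s <- max(as.integer(start), mid - w %/% 2L)
  e <- min(as.integer(end), s + w)
  list(start = s, end = e)
}
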