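# Daylong ambulatory processing: 50-ms non-overlapping framing, the
# five-criterion voice-activity detector, per-frame feature extraction with a
# fixed participant-specific IBIF model, Ps prediction on valid voiced frames,
# and daylong summary statistics and rolling profiles.

#' Voice-activity detection criteria
#'
#' The five inclusive feature ranges a 50-ms frame must satisfy to be voiced:
#' SPL 45--130 dB SPL at 15 cm, f0 70--1000 Hz, autocorrelation peak
#' 0.60--1, subharmonic peak 0.25--1, low-to-high spectral ratio 22--50 dB.
#'
#' @param spl,f0,autocorr_peak,subharmonic_peak,lh_ratio length-2 numeric
#'   ranges (lower, upper).
#' @return object of class `vad_criteria`.
#' @export
vad_criteria <- function(spl = c(45, 130), f0 = c(70, 1000),
                         autocorr_peak = c(0.60, 1),
                         subharmonic_peak = c(0.25, 1),
                         lh_ratio = c(22, 50)) {
  c <- list(spl = spl, f0 = f0, autocorr_peak = autocorr_peak,
            subharmonic_peak = subharmonic_peak, lh_ratio = lh_ratio)
  for (nm in names(c)) {
    if (length(c[[nm]]) != 2L || c[[nm]][1] >= c[[nm]][2]) {
      stop("each criterion must be a (lower, upper) range: ", nm)
    }
  }
  structure(c, class = "vad_criteria")
}

#' Frame a stream into 50-ms non-overlapping frames
#'
#' @param acc a [calibrated_signal] (or numeric with `fs`).
#' @param fs sampling rate when `acc` is numeric.
#' @param frame_s frame length in seconds.
#' @return list with `n_frames` (= floor(duration / frame_s); the trailing
#'   partial frame is dropped), `frame_len` (samples), `starts` (0-based
#'   sample index per frame), `fs`.
#' @export
frame_stream <- function(acc, fs = NULL, frame_s = 0.05) {
  if (inherits(acc, "calibrated_signal")) {
    fs <- acc$fs
    n <- length(acc$samples)
  } else n <- length(acc)
  if (is.null(fs)) stop("fs required")
  frame_len <- as.integer(round(frame_s * fs))
  n_frames <- n %/% frame_len
  list(n_frames = n_frames, frame_len = frame_len,
       starts = (seq_len(n_frames) - 1L) * frame_len, fs = fs)
}

#' Frame-level voicing decision
#'
#' A frame is voiced iff all five features lie inside their (inclusive)
#' criterion ranges; `NA` features fail.
#'
#' @param features data.frame (one or more rows) with columns `spl`, `f0`,
#'   `autocorr_peak`, `subharmonic_peak`, `lh_ratio`.
#' @param criteria a [vad_criteria].
#' @return logical vector, one flag per row.
#' @export
is_voiced <- function(features, criteria = vad_criteria()) {
  stopifnot(inherits(criteria, "vad_criteria"))
  inside <- function(v, r) !is.na(v) & v >= r[1] & v <= r[2]
  inside(features$spl, criteria$spl) &
    inside(features$f0, criteria$f0) &
    inside(features$autocorr_peak, criteria$autocorr_peak) &
    inside(features$subharmonic_peak, criteria$subharmonic_peak) &
    inside(features$lh_ratio, criteria$lh_ratio)
}

#' Process a daylong accelerometer stream
#'
#' For each 50-ms frame: compute the five VAD features (SPL via the
#' participant's ACC-to-SPL mapping); for voiced frames, inverse-filter with
#' the fixed participant IBIF model, compute the vocal-function measures,
#' apply the physiological validity filter, and predict Ps on surviving frames
#' with the participant's fitted model.
#'
#' @param acc daylong ACC [calibrated_signal] (cm/s^2).
#' @param spl_mapping the participant's `spl_mapping`.
#' @param ibif_params the participant's time-invariant [ibif_params].
#' @param ps_model fitted `ps_stepwise_model` or `ps_line_model` (may be
#'   `NULL` to skip prediction).
#' @param criteria a [vad_criteria].
#' @param progress_every print progress every this many frames (0 = silent).
#' @return data.frame, one row per frame: `frame`, `t_start`, VAD features,
#'   `voiced`, glottal measures, `valid`, `reasons`, `ps_est`.
#' @export
process_day <- function(acc, spl_mapping, ibif_params, ps_model = NULL,
                        criteria = vad_criteria(), progress_every = 0) {
  if (is.null(spl_mapping) || is.null(ibif_params)) {
    stop("configuration error: missing participant artifact")
  }
  stopifnot(inherits(acc, "calibrated_signal"))
  fs <- acc$fs
  fr <- frame_stream(acc)
  nf <- fr$n_frames
  fl <- fr$frame_len
  x <- acc$samples
  need_glottal <- is.null(ps_model) ||
    inherits(ps_model, "ps_stepwise_model")
  model_feats <- if (inherits(ps_model, "ps_stepwise_model"))
    ps_model$selected_features else character(0)
  cols <- c("rms", "spl", "f0", "autocorr_peak", "subharmonic_peak",
            "lh_ratio", "cpp", "acfl", "mfdr", "oq", "sq", "h1h2", "hrf",
            "naq")
  out <- as.data.frame(matrix(NA_real_, nf, length(cols),
                              dimnames = list(NULL, cols)))
  voiced <- logical(nf)
  valid <- logical(nf)
  reasons <- character(nf)
  ps_est <- rep(NA_real_, nf)
  spl_lo <- criteria$spl[1]
  for (f in seq_len(nf)) {
    if (progress_every > 0 && f %% progress_every == 0L) {
      message(sprintf("frame %d / %d", f, nf))
    }
    w <- x[(fr$starts[f] + 1L):(fr$starts[f] + fl)]
    rms <- frame_rms(w)
    spl <- acc_to_spl(spl_mapping, rms)
    out$rms[f] <- rms
    out$spl[f] <- spl
    if (spl < spl_lo) next  # cheap gate: cannot be voiced
    p <- f0_autocorrelation(w, fs, fmin = criteria$f0[1],
                            fmax = criteria$f0[2])
    out$f0[f] <- p$f0
    out$autocorr_peak[f] <- p$autocorr_peak
    out$subharmonic_peak[f] <- p$subharmonic_peak
    if (!p$voiced) next
    out$lh_ratio[f] <- lh_ratio(w, fs)
    v <- is_voiced(out[f, , drop = FALSE], criteria)
    voiced[f] <- v
    if (!v) next
    out$cpp[f] <- cpp(w, fs)
    if (need_glottal) {
      g <- tryCatch(inverse_filter(w, ibif_params, fs = fs, f0 = p$f0),
                    error = function(e) NULL)
      if (!is.null(g)) {
        td <- time_domain_features(g)
        sp <- spectral_features(g)
        out$acfl[f] <- td$acfl; out$mfdr[f] <- td$mfdr
        out$oq[f] <- td$oq; out$sq[f] <- td$sq; out$naq[f] <- td$naq
        out$h1h2[f] <- sp$h1h2; out$hrf[f] <- sp$hrf
      }
      vf <- validity_filter(out[f, ], out$f0[f])
      valid[f] <- vf$keep
      reasons[f] <- paste(vf$reasons, collapse = ",")
    } else {
      valid[f] <- !is.na(out$f0[f]) && out$f0[f] <= 500
      if (!valid[f]) reasons[f] <- "F0"
    }
    if (valid[f] && !is.null(ps_model)) {
      ps_est[f] <- tryCatch(predict_ps(ps_model, out[f, , drop = FALSE]),
                            error = function(e) NA_real_)
    }
  }
  data.frame(frame = seq_len(nf) - 1L, t_start = fr$starts / fs,
             out, voiced = voiced, valid = valid, reasons = reasons,
             ps_est = ps_est)
}

# Third standardized moment (population form).
.skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# Histogram mode with fixed-width bins; ties broken toward the lower bin.
.hist_mode <- function(x, width = 0.5, lim = c(0, 40)) {
  x <- pmin(pmax(x, lim[1]), lim[2] - 1e-9)
  bins <- floor((x - lim[1]) / width)
  tab <- table(bins)
  b <- as.integer(names(tab)[which.max(tab)])  # which.max: first = lowest bin
  lim[1] + (b + 0.5) * width
}

#' Daylong summary statistics
#'
#' Phonation time (cumulative seconds and percent of monitored frames) and,
#' per measure over voiced valid frames: mean, SD, skewness (third
#' standardized moment), trimmed minimum/maximum (5th and 95th percentiles),
#' and for Ps the histogram mode (0.5 cm H2O bins over 0--40, ties toward the
#' lower bin).
#'
#' @param records data.frame from [process_day()].
#' @param measures feature columns to summarize alongside `ps_est`.
#' @return object of class `day_summary` (a list).
#' @export
summarize_day <- function(records,
                          measures = c("spl", "cpp", "h1h2")) {
  nf <- nrow(records)
  nv <- sum(records$voiced)
  out <- list(monitoring_duration_h = nf * 0.05 / 3600,
              n_frames = nf, n_voiced = nv,
              phonation_time_cum_s = 0.05 * nv,
              phonation_pct = if (nf > 0) 100 * nv / nf else 0)
  stat_block <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) return(NULL)
    q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
    list(n = length(x), mean = mean(x), sd = stats::sd(x),
         skewness = .skewness(x), p5 = q[1], p95 = q[2])
  }
  ps <- records$ps_est[records$voiced & records$valid]
  b <- stat_block(ps)
  if (!is.null(b)) {
    b$mode <- .hist_mode(ps[is.finite(ps)])
    out$ps <- b
  }
  for (m in intersect(measures, colnames(records))) {
    b <- stat_block(records[[m]][records$voiced])
    if (!is.null(b)) out[[m]] <- b
  }
  structure(out, class = "day_summary")
}

#' @export
print.day_summary <- function(x, ...) {
  cat(sprintf("<day_summary> %.2f h monitored, phonation %.1f%% (%.1f s)\n",
              x$monitoring_duration_h, x$phonation_pct,
              x$phonation_time_cum_s))
  if (!is.null(x$ps)) {
    cat(sprintf(
      "  Ps [cmH2O]: mean %.2f sd %.2f mode %.2f skew %.2f p5 %.2f p95 %.2f\n",
      x$ps$mean, x$ps$sd, x$ps$mode, x$ps$skewness, x$ps$p5, x$ps$p95))
  }
  invisible(x)
}

#' Rolling 5-minute profile
#'
#' Percent phonation plus the median and 95th percentile of a measure over
#' sliding windows (default 5 min at 30-s steps). Windows truncated at the
#' stream end are flagged.
#'
#' @param records data.frame from [process_day()] (time-ordered).
#' @param window_s,step_s window and step in seconds.
#' @param measure column to profile (over voiced valid frames).
#' @return data.frame with `t_start`, `t_end`, `truncated`, `pct_phonation`,
#'   `median`, `p95`.
#' @export
rolling_profile <- function(records, window_s = 300, step_s = 30,
                            measure = "ps_est") {
  total <- nrow(records) * 0.05
  starts <- seq(0, max(total - step_s, 0), by = step_s)
  rows <- lapply(starts, function(s) {
    e <- min(s + window_s, total)
    sel <- records$t_start >= s & records$t_start < e
    v <- records$voiced[sel]
    x <- records[[measure]][sel & records$voiced & records$valid]
    x <- x[is.finite(x)]
    data.frame(t_start = s, t_end = e, truncated = (s + window_s) > total,
               pct_phonation = if (length(v)) 100 * mean(v) else NA_real_,
               median = if (length(x)) stats::median(x) else NA_real_,
               p95 = if (length(x)) stats::quantile(x, 0.95, names = FALSE)
                     else NA_real_)
  })
  do.call(rbind, rows)
}

#' Select the participant's ambulatory IBIF segment from the laboratory session
#'
#' The time-invariant ambulatory IBIF model is taken from the laboratory /a/
#' vowel with the highest reference Ps in the comfortable pitch condition.
#'
#' @param segments data.frame with `vowel`, `pitch`, `ps_ref` per segment.
#' @return row index of the selected segment.
#' @export
select_ambulatory_ibif_segment <- function(segments) {
  cand <- which(segments$vowel == "a" &
                  segments$pitch == "comfortable" &
                  is.finite(segments$ps_ref))
  if (length(cand) == 0L) stop("no /a/ comfortable-pitch segment available")
  cand[which.max(segments$ps_ref[cand])]
}

#' Write frame records to TSV
#' @param records data.frame from [process_day()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
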