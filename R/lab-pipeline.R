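# End-to-end laboratory processing: resample/align the ACC channel, segment
# vowels and intraoral-pressure plateaus, compute reference Ps, and extract
# the per-segment vocal function measures used by the three Ps estimators.

#' Process a laboratory calibration session into a segment feature table
#'
#' Steps: (1) if the ACC channel is not at the laboratory rate, up-sample it
#' and align it to the microphone by cross-correlation; (2) detect vowel
#' segments on the microphone (or take the provided ground-truth segments);
#' (3) detect intraoral-pressure plateaus and compute reference Ps per vowel;
#' (4) per segment, compute SPL and the ten vocal function measures (the
#' first three from the raw ACC middle-50-ms window, the remaining seven from
#' the inverse-filtered glottal airflow over the full segment); (5) apply the
#' physiological validity filter.
#'
#' @param session list with [calibrated_signal]s `mic`, `flow`, `iop`, and
#'   `acc` (or `acc_raw` at 11,025 Hz); a synthetic session from
#'   [synthesize_lab_session()] works directly.
#' @param ibif an [ibif_params] for inverse filtering (participant-specific).
#' @param use_truth_segments use the generator's segment bounds and labels
#'   instead of microphone segmentation (synthetic sessions only).
#' @param segments optional externally supplied segment table with `start`,
#'   `end` (0-based samples) and optional `vowel`, `pitch` labels.
#' @return data.frame, one row per segment: labels, bounds, `ps_ref`,
#'   `ps_flag`, `spl`, the ten measures, `valid`, `reasons`.
#' @export
process_lab_session <- function(session, ibif, use_truth_segments = FALSE,
                                segments = NULL) {
  mic <- session$mic
  fs <- mic$fs
  acc <- session$acc
  if (is.null(acc) && !is.null(session$acc_raw)) {
    acc <- resample_signal(session$acc_raw, fs)
    lag <- align_acc_to_mic(acc, mic)
    acc <- apply_lag(acc, lag)
  }
  if (is.null(acc)) stop("session must provide an acc or acc_raw channel")
  if (abs(acc$fs - fs) > 1e-9) {
    acc <- resample_signal(acc, fs)
    lag <- align_acc_to_mic(acc, mic)
    acc <- apply_lag(acc, lag)
  }
  if (is.null(segments)) {
    if (use_truth_segments) {
      segments <- session$truth
    } else {
      segments <- segment_vowels(mic)
      segments <- .label_segments(segments, session$truth)
    }
  }
  plateaus <- detect_iop_plateaus(session$iop, segments)
  segments <- reference_ps_table(segments, plateaus)
  n <- nrow(segments)
  feat <- data.frame(spl = rep(NA_real_, n), rms = NA_real_, f0 = NA_real_,
                     cpp = NA_real_, acfl = NA_real_, mfdr = NA_real_,
                     oq = NA_real_, sq = NA_real_, h1h2 = NA_real_,
                     hrf = NA_real_, naq = NA_real_)
  valid <- logical(n)
  reasons <- character(n)
  xm <- mic$samples
  xa <- acc$samples
  for (i in seq_len(n)) {
    s <- segments$start[i]; e <- segments$end[i]
    w <- segment_mid_window(s, e, fs)
    mid_m <- xm[(w$start + 1L):w$end]
    mid_a <- xa[(w$start + 1L):w$end]
    feat$spl[i] <- tryCatch(spl_from_mic(mid_m), error = function(e) NA_real_)
    feat$rms[i] <- frame_rms(mid_a)
    p <- f0_autocorrelation(mid_a, fs, fmin = 70, fmax = 1000)
    feat$f0[i] <- p$f0
    feat$cpp[i] <- tryCatch(cpp(mid_a, fs), error = function(e) NA_real_)
    seg_a <- xa[(s + 1L):e]
    g <- tryCatch(inverse_filter(seg_a, ibif, fs = fs, f0 = p$f0),
                  error = function(e) NULL)
    if (!is.null(g)) {
      td <- time_domain_features(g)
      sp <- spectral_features(g)
      feat$acfl[i] <- td$acfl; feat$mfdr[i] <- td$mfdr
      feat$oq[i] <- td$oq; feat$sq[i] <- td$sq; feat$naq[i] <- td$naq
      feat$h1h2[i] <- sp$h1h2; feat$hrf[i] <- sp$hrf
    }
    vf <- validity_filter(feat[i, ], feat$f0[i])
    valid[i] <- vf$keep
    reasons[i] <- paste(vf$reasons, collapse = ",")
  }
  cbind(segments, feat, data.frame(valid = valid, reasons = reasons))
}

# Attach vowel/pitch labels to detected segments by overlap with the truth
# table (elicitation protocol order); unlabeled segments get NA.
.label_segments <- function(segments, truth) {
  segments$vowel <- NA_character_
  segments$pitch <- NA_character_
  if (is.null(truth)) return(segments)
  for (i in seq_len(nrow(segments))) {
    ov <- pmin(segments$end[i], truth$end) - pmax(segments$start[i], truth$start)
    j <- which.max(ov)
    if (length(j) && ov[j] > 0) {
      segments$vowel[i] <- truth$vowel[j]
      segments$pitch[i] <- truth$pitch[j]
    }
  }
  segments
}

#' Write a segment feature table to TSV
#'
#' Columns follow the package's canonical names (`rms_cms2`, `f0_hz`,
#' `cpp_db`, `spl_db15cm`, `acfl_mls`, `mfdr_ls2`, `oq_pct`, `sq_pct`,
#' `h1h2_db`, `hrf_db`, `naq`).
#'
#' @param features data.frame from [process_lab_session()].
#' @param path output path.
#' @param session session identifier written per row.
#' @param fs sampling rate used to derive seconds when the table carries only
#'   sample bounds.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(features, path, session = "session1",
                                fs = 20000) {
  start_s <- if (!is.null(features$start_s)) features$start_s
             else features$start / fs
  end_s <- if (!is.null(features$end_s)) features$end_s
           else features$end / fs
  vow <- if (!is.null(features$vowel)) features$vowel else NA_character_
  pit <- if (!is.null(features$pitch)) features$pitch else NA_character_
  fs_out <- data.frame(session = session,
                       segment_id = seq_len(nrow(features)) - 1L,
                       start_s = start_s,
                       end_s = end_s,
                       vowel = vow,
                       pitch_condition = pit,
                       ps_ref_cmH2O = features$ps_ref,
                       rms_cms2 = features$rms, f0_hz = features$f0,
                       cpp_db = features$cpp, spl_db15cm = features$spl,
                       acfl_mls = features$acfl, mfdr_ls2 = features$mfdr,
                       oq_pct = features$oq, sq_pct = features$sq,
                       h1h2_db = features$h1h2, hrf_db = features$hrf,
                       naq = features$naq,
                       qc_flags = features$reasons)
  utils::write.table(fs_out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
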