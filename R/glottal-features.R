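# The seven glottal-airflow measures: AC flow (ACFL), maximum flow declination
# rate (MFDR), open quotient (OQ), speed quotient (SQ), H1-H2, harmonic
# richness factor (HRF), and normalized amplitude quotient (NAQ). Cycles are
# anchored at closure instants (negative-derivative peaks); the opening instant
# is the rising crossing of (cycle minimum + open_threshold * peak-to-peak),
# since true opening is unobservable in inverse-filtered flow.

#' Time-domain glottal airflow measures
#'
#' Per-cycle values averaged over complete cycles. ACFL is the peak-to-peak
#' flow (mL/s); MFDR the magnitude of the most negative flow derivative
#' (L/s^2); OQ the open time over the cycle period (%); SQ the opening over
#' closing time (100 * t_op / t_cp, %); NAQ = (ACFL / MFDR) / period
#' (unitless, consistent mL units cancel).
#'
#' @param g a `glottal_waveform` from [inverse_filter()] (or a list with
#'   `flow`, `fs`, `f0`).
#' @param open_threshold fraction of the cycle peak-to-peak above the cycle
#'   minimum defining the opening instant.
#' @return one-row data.frame `acfl`, `mfdr`, `oq`, `sq`, `naq`, `f0`,
#'   `n_cycles` (all `NA` with `n_cycles = 0` when no cycles are found).
#' @export
time_domain_features <- function(g, open_threshold = 0.10) {
  flow <- g$flow
  fs <- g$fs
  f0 <- g$f0
  nd <- data.frame(acfl = NA_real_, mfdr = NA_real_, oq = NA_real_,
                   sq = NA_real_, naq = NA_real_, f0 = NA_real_, n_cycles = 0L)
  if (is.null(f0) || is.na(f0)) {
    p <- f0_autocorrelation(flow, fs, fmin = 50, fmax = 1000)
    f0 <- p$f0
  }
  if (is.na(f0)) return(nd)
  closures <- .closure_instants(flow, fs, f0)
  if (length(closures) < 4L) return(nd)
  d <- diff(flow) * fs                     # mL/s^2 at samples i+1/2
  per_cycle <- list()
  ci <- 0L
  for (k in seq_len(length(closures) - 1L)) {
    s <- closures[k]; e <- closures[k + 1L]
    period <- (e - s) / fs
    if (period <= 0) next
    cyc <- flow[(s + 1L):e]                # cycle: closed phase then pulse
    p2p <- max(cyc) - min(cyc)
    if (p2p <= 0) next
    thr <- min(cyc) + open_threshold * p2p
    pk <- which.max(cyc)
    # opening: last upward crossing of thr before the peak
    pre <- which(cyc[seq_len(pk)] <= thr)
    if (length(pre) == 0L) next
    open_i <- max(pre)
    # fractional crossing refinement
    if (open_i < pk) {
      y0 <- cyc[open_i]; y1 <- cyc[open_i + 1L]
      frac <- if (y1 > y0) (thr - y0) / (y1 - y0) else 0
    } else frac <- 0
    t_open <- (open_i - 1 + frac) / fs
    t_peak <- (pk - 1) / fs
    t_close <- period                      # cycle ends at the next closure
    t_o <- t_close - t_open
    if (t_o <= 0 || t_o >= period) next
    t_op <- t_peak - t_open
    t_cp <- t_close - t_peak
    if (t_op <= 0 || t_cp <= 0) next
    mfdr_mls2 <- max(-d[(s + 1L):(e - 1L)])
    if (mfdr_mls2 <= 0) next
    ci <- ci + 1L
    per_cycle[[ci]] <- c(acfl = p2p,
                         mfdr = mfdr_mls2 * MLS2_TO_LS2,
                         oq = 100 * t_o / period,
                         sq = 100 * t_op / t_cp,
                         naq = (p2p / mfdr_mls2) / period,
                         period = period)
  }
  if (ci < 3L) return(nd)
  m <- colMeans(do.call(rbind, per_cycle))
  data.frame(acfl = m[["acfl"]], mfdr = m[["mfdr"]], oq = m[["oq"]],
             sq = m[["sq"]], naq = m[["naq"]], f0 = 1 / m[["period"]],
             n_cycles = ci)
}

# Closure instants: prominent local peaks of the negative flow derivative, at
# least half a nominal period apart. The threshold is set relative to the
# typical per-cycle closure peak (the m-th largest local maximum, m ~ the
# expected cycle count) rather than the global maximum, so an isolated edge
# or filtering artifact cannot mask the real closures. Half a period at each
# edge is excluded. Returns 1-based sample indices.
.closure_instants <- function(flow, fs, f0) {
  n <- length(flow)
  if (n < 8L) return(integer(0))
  d <- diff(flow) * fs
  neg <- -d
  nd <- length(neg)
  edge <- min(as.integer(round(0.5 * fs / f0)), nd %/% 4L)
  if (edge > 0L) {
    neg[seq_len(edge)] <- 0
    neg[(nd - edge + 1L):nd] <- 0
  }
  loc <- which(neg[2:(nd - 1L)] >= neg[1:(nd - 2L)] &
                 neg[2:(nd - 1L)] > neg[3:nd]) + 1L
  loc <- loc[neg[loc] > 0]
  if (length(loc) == 0L) return(integer(0))
  m <- max(1L, as.integer(floor(0.7 * n * f0 / fs)))
  vals <- sort(neg[loc], decreasing = TRUE)
  thr <- 0.5 * vals[min(m, length(vals))]
  if (!is.finite(thr) || thr <= 0) return(integer(0))
  min_gap <- as.integer(floor(0.5 * fs / f0))
  cand <- loc[neg[loc] >= thr]
  cand <- cand[order(-neg[cand])]
  sel <- integer(0)
  for (i in cand) {
    if (length(sel) == 0L || all(abs(sel - i) >= min_gap)) sel <- c(sel, i)
  }
  sort(sel)
}

#' Spectral glottal airflow measures: H1-H2 and HRF
#'
#' Harmonic magnitudes at k * f0 from an exact DFT of the Hann-windowed
#' waveform (the f0 is first refined locally to maximize |H1|). H1-H2 is the
#' dB difference of the first two harmonics. HRF is the power ratio of
#' harmonics 2--8 to the first harmonic in dB,
#' `10 * log10(sum_{k=2..8} P_k / P_1)`; set `hrf_literal = TRUE` for the
#' literal sum-of-log-magnitudes reading.
#'
#' @param g a `glottal_waveform` (window of at least 4 periods).
#' @param n_harmonics harmonics used for HRF (default 8).
#' @param hrf_literal use the literal sum-of-log-magnitude-ratios form.
#' @return one-row data.frame `h1h2`, `hrf`, `n_harmonics_used`, `flag_nyquist`.
#' @export
spectral_features <- function(g, n_harmonics = 8, hrf_literal = FALSE) {
  flow <- g$flow
  fs <- g$fs
  f0 <- g$f0
  if (is.null(f0) || is.na(f0)) {
    f0 <- f0_autocorrelation(flow, fs, fmin = 50, fmax = 1000)$f0
  }
  nd <- data.frame(h1h2 = NA_real_, hrf = NA_real_, n_harmonics_used = 0L,
                   flag_nyquist = FALSE)
  n <- length(flow)
  if (is.na(f0) || n < 4 * fs / f0) return(nd)
  w <- (flow - mean(flow)) * hann_window(n)
  dft_mag <- function(fq) {
    ph <- -2i * pi * fq * (0:(n - 1L)) / fs
    Mod(sum(w * exp(ph))) / n
  }
  # refine f0 by local search maximizing |H1|
  cand <- f0 * seq(0.95, 1.05, length.out = 21)
  f0r <- cand[which.max(vapply(cand, dft_mag, numeric(1)))]
  kmax <- max(2L, min(as.integer(n_harmonics), floor((fs / 2) / f0r)))
  flag <- kmax < n_harmonics
  mags <- vapply(seq_len(kmax), function(k) dft_mag(k * f0r), numeric(1))
  mags <- pmax(mags, 1e-300)
  h1h2 <- 20 * log10(mags[1] / mags[2])
  if (hrf_literal) {
    hrf <- sum(20 * log10(mags[2:kmax] / mags[1]))
  } else {
    hrf <- 10 * log10(sum(mags[2:kmax]^2) / mags[1]^2)
  }
  data.frame(h1h2 = h1h2, hrf = hrf, n_harmonics_used = kmax,
             flag_nyquist = flag)
}

#' Physiological validity filter for glottal features
#'
#' A segment or frame is kept only if ACFL >= 1 mL/s, MFDR >= 1 L/s^2, OQ is
#' within 0--100%, and f0 <= 500 Hz (glottal inverse filtering is unreliable
#' above that). Reason codes enumerate every violated rule; `NA` features
#' violate their rule.
#'
#' @param features one-row data.frame (or list) with `acfl`, `mfdr`, `oq`.
#' @param f0 fundamental frequency in Hz.
#' @return list with `keep` (logical) and `reasons` (character vector of
#'   `"ACFL"`, `"MFDR"`, `"OQ"`, `"F0"`).
#' @export
validity_filter <- function(features, f0) {
  reasons <- character(0)
  bad <- function(v, ok) is.null(v) || is.na(v) || !ok(v)
  if (bad(features$acfl, function(v) v >= 1)) reasons <- c(reasons, "ACFL")
  if (bad(features$mfdr, function(v) v >= 1)) reasons <- c(reasons, "MFDR")
  if (bad(features$oq, function(v) v >= 0 && v <= 100)) reasons <- c(reasons, "OQ")
  if (bad(f0, function(v) v <= 500)) reasons <- c(reasons, "F0")
  list(keep = length(reasons) == 0L, reasons = reasons)
}
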