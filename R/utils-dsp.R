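# Low-level DSP helpers shared across the package. No external DSP package is
# assumed: resampling, band-pass filtering and correlation are built on stats::fft.

next_pow2 <- function(n) {
  n <- max(1L, as.integer(ceiling(n)))
  2L^as.integer(ceiling(log2(n)))
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

blackman_window <- function(n) {
  if (n == 1L) return(1)
  k <- (seq_len(n) - 1L) / (n - 1L)
  0.42 - 0.5 * cos(2 * pi * k) + 0.08 * cos(4 * pi * k)
}

sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))

db <- function(x, ref = 1) 20 * log10(x / ref)

# Run `code` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Raised-cosine ramp 0 -> 1 for f in [a, b].
.ramp_up <- function(f, a, b) {
  r <- (f - a) / max(b - a, 1e-12)
  r <- pmin(pmax(r, 0), 1)
  0.5 - 0.5 * cos(pi * r)
}

#' Zero-phase FFT-domain band-pass filter
#'
#' Applies a zero-phase band-pass with raised-cosine transition bands by
#' windowing the spectrum. Used for the 50--4000 Hz glottal-flow band and the
#' 50--1100 Hz oral-airflow comparison band.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param f_lo,f_hi passband edges in Hz; `NULL` disables that edge.
#' @param trans transition width in Hz (default: 40% of `f_lo` below, 10% of
#'   `f_hi` above).
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
fft_bandpass <- function(x, fs, f_lo = NULL, f_hi = NULL, trans = NULL) {
  n <- length(x)
  if (n < 4L) return(x - mean(x))
  nfft <- next_pow2(n + max(512L, round(fs * 0.02)))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  f <- (seq_len(nfft) - 1L) * fs / nfft
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  g <- rep(1, nfft)
  if (!is.null(f_lo) && f_lo > 0) {
    tw <- if (is.null(trans)) 0.4 * f_lo else trans
    g <- g * .ramp_up(f, max(f_lo - tw, 0), f_lo)
  }
  if (!is.null(f_hi) && f_hi < fs / 2) {
    tw <- if (is.null(trans)) 0.1 * f_hi else trans
    g <- g * (1 - .ramp_up(f, f_hi, min(f_hi + tw, fs / 2)))
  }
  Re(stats::fft(X * g, inverse = TRUE) / nfft)[seq_len(n)]
}

# Best small-denominator rational approximation of a positive ratio.
.rational_ratio <- function(ratio, max_den = 2000L) {
  # continued-fraction expansion
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  x <- ratio
  for (i in 1:64) {
    a <- floor(x)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - ratio) < 1e-12) break
    frac <- x - a
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  list(p = as.integer(p1), q = as.integer(q1))
}

#' Polyphase rational-rate resampling of a numeric vector
#'
#' Band-limited resampling by an exact rational factor p/q (e.g. 11025 to
#' 20000 Hz is 800/441) using a Blackman-windowed sinc anti-aliasing kernel in
#' polyphase form. Each polyphase branch is normalized to unit sum so DC is
#' preserved exactly.
#'
#' @param x numeric vector.
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @param half_width kernel half-width in input (or output, if decimating)
#'   sample periods; larger is sharper but slower.
#' @return resampled numeric vector of length `round(length(x) * fs_out/fs_in)`
#'   (within one sample).
#' @keywords internal
resample_core <- function(x, fs_in, fs_out, half_width = 10L) {
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive")
  if (abs(fs_in - fs_out) < 1e-9) return(x)
  r <- .rational_ratio(fs_out / fs_in)
  p <- r$p; q <- r$q
  mx <- max(p, q)
  M <- as.integer(half_width) * mx          # kernel half-width, upsampled domain
  L <- 2L * M + 1L
  n0 <- seq_len(L) - 1L
  h <- sinc((n0 - M) / mx) * blackman_window(L)
  # normalize each polyphase branch -> exact DC preservation
  for (ph in 0:(p - 1L)) {
    idx <- seq(ph + 1L, L, by = p)
    s <- sum(h[idx])
    if (abs(s) > 1e-12) h[idx] <- h[idx] / s
  }
  n_in <- length(x)
  n_out <- as.integer(round(n_in * p / q))
  m <- 0:(n_out - 1L)
  tq <- m * q + M
  i0 <- tq %/% p                             # input index (0-based) of tap k = 0
  ph <- tq %% p
  Kt <- as.integer(ceiling(L / p))
  pad <- max(Kt, as.integer(ceiling(M / p))) + 2L
  xp <- c(rep(0, pad), x, rep(0, pad))
  y <- numeric(n_out)
  for (k in 0:(Kt - 1L)) {
    hidx <- ph + p * k + 1L
    ok <- hidx <= L
    coef <- numeric(n_out)
    coef[ok] <- h[hidx[ok]]
    y <- y + coef * xp[i0 - k + pad + 1L]
  }
  y
}

# Cross-correlation lag search: returns the lag l in [-max_lag, max_lag]
# maximizing sum_t a[t] * b[t - l] (positive lag = `a` delayed relative to `b`).
xcorr_best_lag <- function(a, b, max_lag) {
  n <- length(a)
  stopifnot(length(b) == n, max_lag < n)
  nfft <- next_pow2(2L * n)
  A <- stats::fft(c(a, rep(0, nfft - n)))
  B <- stats::fft(c(b, rep(0, nfft - n)))
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE) / nfft)
  # cc[l + 1] = sum_s a[s + l] b[s] for l >= 0; negative lags wrap to the end.
  # If a[t] = b[t - k] (a delayed by k) the peak sits at l = k.
  lags <- c(0:max_lag, -(max_lag:1))
  pos <- c(seq_len(max_lag + 1L), nfft - (max_lag:1) + 1L)
  vals <- cc[pos]
  best <- which.max(vals)
  list(lag = lags[best], value = vals[best], lags = lags, values = vals)
}

# Normalized autocorrelation r[k], k = 0..n-1 (r[1] corresponds to lag 0).
autocorr_norm <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  e <- sum(x^2)
  if (e <= 0) return(rep(0, n))
  nfft <- next_pow2(2L * n)
  S <- Mod(stats::fft(c(x, rep(0, nfft - n))))^2
  r <- Re(stats::fft(S, inverse = TRUE) / nfft)[seq_len(n)]
  r / r[1]
}

# Parabolic interpolation around a discrete peak at index i (1-based) of y.
# Returns list(pos, val) with fractional index.
.parabolic_peak <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(list(pos = i, val = y[i]))
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (abs(denom) < 1e-30) return(list(pos = i, val = y[i]))
  d <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  d <- max(min(d, 0.5), -0.5)
  list(pos = i + d, val = y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * d)
}
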