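#' Calibrated physical-unit signal
#'
#' Container for a uniformly sampled time series in physical units. The four
#' laboratory channels (microphone in Pa, oral airflow in mL/s, intraoral
#' pressure in cm H2O, accelerometer in cm/s^2) and the ambulatory
#' accelerometer stream are all represented this way. Laboratory channels run
#' at 20 kHz; the raw ambulatory accelerometer runs at 11,025 Hz until
#' resampled.
#'
#' @param samples numeric vector in channel units; must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param channel one of `"MIC"`, `"FLOW"`, `"IOP"`, `"ACC"`.
#' @param units unit string; defaults to the conventional unit of the channel.
#' @return an object of class `calibrated_signal`.
#' @export
calibrated_signal <- function(samples, fs,
                              channel = c("ACC", "MIC", "FLOW", "IOP"),
                              units = NULL) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (is.null(units)) units <- channel_units(channel)
  structure(list(samples = samples, fs = fs, channel = channel, units = units),
            class = "calibrated_signal")
}

#' @export
print.calibrated_signal <- function(x, ...) {
  cat(sprintf("<calibrated_signal> %s [%s], fs = %g Hz, %d samples (%.3f s)\n",
              x$channel, x$units, x$fs, length(x$samples),
              length(x$samples) / x$fs))
  invisible(x)
}

#' Conventional units per channel
#' @param channel channel code.
#' @return unit string.
#' @export
channel_units <- function(channel) {
  switch(channel,
         MIC = "Pa", FLOW = "mL/s", IOP = "cmH2O", ACC = "cm/s2",
         stop("unknown channel: ", channel))
}

#' Sensor calibration line (units per volt)
#'
#' @param slope units per volt; must be nonzero.
#' @param intercept offset in channel units.
#' @return an object of class `calibration_line`.
#' @export
calibration_line <- function(slope, intercept = 0) {
  if (!is.finite(slope) || slope == 0) stop("invalid calibration: slope must be nonzero")
  structure(list(slope = slope, intercept = intercept), class = "calibration_line")
}

#' Apply a calibration line to a raw voltage series
#'
#' Element-wise affine map `slope * raw + intercept` converting an uncalibrated
#' voltage recording to physical units.
#'
#' @param raw numeric voltage vector (finite).
#' @param line a [calibration_line].
#' @param fs sampling rate of `raw` in Hz.
#' @param channel channel code of the calibrated output.
#' @return a [calibrated_signal].
#' @export
apply_calibration <- function(raw, line, fs, channel = "ACC") {
  if (!inherits(line, "calibration_line")) stop("line must be a calibration_line")
  if (!all(is.finite(raw))) stop("raw voltages must be finite")
  calibrated_signal(line$slope * raw + line$intercept, fs = fs, channel = channel)
}

#' Fit a calibration line through known reference points
#'
#' Least-squares line mapping measured voltages to known physical values (for
#' example, the five-point intraoral pressure calibration at 0, 5, 10, 15 and
#' 20 cm H2O). With exactly two distinct points the line interpolates them.
#'
#' @param known_inputs physical reference values (channel units).
#' @param measured_voltages voltages observed at those references.
#' @return a [calibration_line].
#' @export
fit_calibration_line <- function(known_inputs, measured_voltages) {
  stopifnot(length(known_inputs) == length(measured_voltages),
            length(known_inputs) >= 2L)
  v <- as.numeric(measured_voltages)
  u <- as.numeric(known_inputs)
  if (stats::sd(v) == 0) stop("degenerate fit: all voltages identical")
  slope <- sum((v - mean(v)) * (u - mean(u))) / sum((v - mean(v))^2)
  calibration_line(slope, mean(u) - slope * mean(v))
}

#' Band-limited resampling of a calibrated signal
#'
#' Polyphase rational-rate resampling (for example 11,025 to 20,000 Hz is the
#' exact ratio 800/441). Duration is preserved within one sample period and DC
#' exactly.
#'
#' @param sig a [calibrated_signal] (or plain numeric vector if `fs` given).
#' @param target_fs target sampling rate in Hz (> 0).
#' @param fs input rate when `sig` is a plain vector.
#' @return a [calibrated_signal] at `target_fs`.
#' @export
resample_signal <- function(sig, target_fs, fs = NULL) {
  if (target_fs <= 0) stop("target_fs must be > 0")
  if (inherits(sig, "calibrated_signal")) {
    y <- resample_core(sig$samples, sig$fs, target_fs)
    calibrated_signal(y, fs = target_fs, channel = sig$channel, units = sig$units)
  } else {
    if (is.null(fs)) stop("fs required for plain numeric input")
    calibrated_signal(resample_core(as.numeric(sig), fs, target_fs),
                      fs = target_fs)
  }
}

#' Align the accelerometer signal to the microphone by cross-correlation
#'
#' Returns the integer lag (in samples, positive = ACC delayed relative to the
#' microphone) maximizing the cross-correlation between the two signals. The
#' search is bounded to +/- `max_lag_s` seconds; acquisition offsets are
#' sub-second in practice.
#'
#' @param acc,mic [calibrated_signal]s at the same sampling rate (ACC
#'   up-sampled to the laboratory rate first).
#' @param max_lag_s lag search bound in seconds.
#' @return integer lag in samples.
#' @export
align_acc_to_mic <- function(acc, mic, max_lag_s = 1) {
  a <- if (inherits(acc, "calibrated_signal")) acc$samples else as.numeric(acc)
  b <- if (inherits(mic, "calibrated_signal")) mic$samples else as.numeric(mic)
  fs <- if (inherits(acc, "calibrated_signal")) acc$fs else
    if (inherits(mic, "calibrated_signal")) mic$fs else
      stop("at least one input must be a calibrated_signal to infer fs")
  if (inherits(acc, "calibrated_signal") && inherits(mic, "calibrated_signal") &&
      abs(acc$fs - mic$fs) > 1e-9) {
    stop("acc and mic must share the same sampling rate")
  }
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  if (sum(a^2) <= 0 || sum(b^2) <= 0) stop("alignment undefined: silent input")
  max_lag <- min(as.integer(round(max_lag_s * fs)), n - 1L)
  xcorr_best_lag(a, b, max_lag)$lag
}

#' Shift a signal by an integer lag
#'
#' Compensates an alignment lag: a positive `lag` (signal delayed) shifts the
#' series earlier by `lag` samples, zero-padding the tail.
#'
#' @param x numeric vector or [calibrated_signal].
#' @param lag integer lag in samples.
#' @return same type as `x`.
#' @export
apply_lag <- function(x, lag) {
  if (inherits(x, "calibrated_signal")) {
    x$samples <- apply_lag(x$samples, lag)
    return(x)
  }
  n <- length(x)
  lag <- as.integer(lag)
  if (lag == 0L) return(x)
  if (lag > 0L) c(x[(lag + 1L):n], rep(0, lag))
  else c(rep(0, -lag), x[seq_len(n + lag)])
}
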