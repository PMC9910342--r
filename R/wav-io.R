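# Minimal RIFF/WAVE reader and writer (PCM16 and IEEE float32, mono). No
# pre-installed package in the target image provides WAV I/O, so the format is
# handled directly; sidecar JSON carries channel, units, fs and calibration.

#' Write a calibrated signal to a WAV file plus sidecar JSON
#'
#' @param sig a [calibrated_signal].
#' @param path output `.wav` path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param format `"float32"` (default; preserves physical units exactly) or
#'   `"pcm16"` (samples scaled by `pcm_scale`).
#' @param pcm_scale full-scale physical value for `"pcm16"`.
#' @param calibration optional [calibration_line] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_wav_signal <- function(sig, path, format = c("float32", "pcm16"),
                             pcm_scale = NULL, calibration = NULL) {
  stopifnot(inherits(sig, "calibrated_signal"))
  format <- match.arg(format)
  x <- sig$samples
  fs <- as.integer(round(sig$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    if (is.null(pcm_scale)) pcm_scale <- max(abs(x), 1e-12)
    q <- as.integer(pmax(pmin(round(x / pcm_scale * 32767), 32767), -32768))
    nbytes <- 2L; fmt_code <- 1L; bits <- 16L
  } else {
    nbytes <- 4L; fmt_code <- 3L; bits <- 32L
  }
  data_len <- length(x) * nbytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * nbytes), con, size = 4, endian = "little")
  writeBin(nbytes, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (format == "pcm16") writeBin(q, con, size = 2, endian = "little")
  else writeBin(as.numeric(x), con, size = 4, endian = "little")
  side <- list(channel = sig$channel, units = sig$units, fs = sig$fs,
               format = format)
  if (format == "pcm16") side$pcm_scale <- pcm_scale
  if (!is.null(calibration)) {
    side$calibration <- list(slope = calibration$slope,
                             intercept = calibration$intercept)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibrated signal written by [write_wav_signal()]
#'
#' @param path `.wav` path with a `<path>.json` sidecar.
#' @return a [calibrated_signal].
#' @export
read_wav_signal <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt_code <- NA_integer_; fs <- NA_real_; bits <- NA_integer_; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16L) invisible(readBin(con, "raw", sz - 16L))
    } else if (identical(id, "data")) {
      if (fmt_code == 1L && bits == 16L) {
        x <- readBin(con, "integer", sz / 2L, size = 2, signed = TRUE,
                     endian = "little") / 32767
        if (!is.null(side$pcm_scale)) x <- x * side$pcm_scale
      } else if (fmt_code == 3L && bits == 32L) {
        x <- readBin(con, "numeric", sz / 4L, size = 4, endian = "little")
      } else stop("unsupported WAV encoding")
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(x)) stop("no data chunk in ", path)
  calibrated_signal(x, fs = fs, channel = side$channel, units = side$units)
}
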