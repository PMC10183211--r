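#' Read and write mono WAV files
#'
#' Minimal RIFF/WAVE reader and writer for mono audio: 32-bit IEEE float
#' (format 3, the interchange default so calibrated pressures survive
#' round-trips) or 16-bit PCM (format 1). A calibration factor converts
#' between file units and micropascal: `read_wav()` multiplies samples by
#' `upa_per_unit` and marks the segment calibrated when the factor is given.
#'
#' @param segment An [audio_segment()].
#' @param path WAV file path.
#' @param format \code{"float32"} (default) or \code{"pcm16"} (samples must
#'   be within [-1, 1]).
#' @param upa_per_unit Calibration factor, uPa per file unit. When writing a
#'   calibrated segment the samples are divided by this factor first.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns an
#'   [audio_segment()].
#' @export
write_wav <- function(segment, path, format = c("float32", "pcm16"),
                      upa_per_unit = 1) {
  format <- match.arg(format)
  stopifnot(inherits(segment, "audio_segment"))
  x <- segment$samples
  if (segment$calibrated) x <- x / upa_per_unit
  fs <- as.integer(round(segment$sample_rate))
  if (format == "float32") {
    fmt_code <- 3L; bits <- 32L
    payload_writer <- function(con) writeBin(x, con, size = 4, endian = "little")
    data_bytes <- 4L * length(x)
  } else {
    if (max(abs(x)) > 1) stop("pcm16 requires samples within [-1, 1]")
    fmt_code <- 1L; bits <- 16L
    ints <- as.integer(round(x * 32767))
    payload_writer <- function(con) writeBin(ints, con, size = 2, endian = "little")
    data_bytes <- 2L * length(x)
  }
  block <- as.integer(bits / 8)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * block), con, size = 4, endian = "little")
  writeBin(block, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  payload_writer(con)
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path, upa_per_unit = NULL) {
  con <- file(path, "rb"); on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt_code <- NULL; fs <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      if (nch != 1) stop("only mono WAV is supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      if (is.null(fmt_code)) stop("malformed WAV: data before fmt chunk")
      if (fmt_code == 3 && bits == 32) {
        samples <- readBin(con, numeric(), n = size / 4, size = 4,
                           endian = "little")
      } else if (fmt_code == 1 && bits == 16) {
        samples <- readBin(con, integer(), n = size / 2, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else stop("unsupported WAV encoding (need float32 or pcm16 mono)")
      break
    } else {
      readBin(con, raw(), n = size + size %% 2)
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  if (!is.null(upa_per_unit))
    audio_segment(samples * upa_per_unit, fs, calibrated = TRUE)
  else
    audio_segment(samples, fs, calibrated = FALSE)
}
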