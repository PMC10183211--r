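#' Synthetic audio sources
#'
#' Simple generators standing in for field recordings when exercising the
#' stimulus-construction and characterization chain: a pure tone of given rms
#' pressure and band-limited Gaussian noise.
#'
#' @param freq_hz Tone frequency in Hz.
#' @param duration_s Duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param rms Root-mean-square amplitude (uPa if \code{calibrated}).
#' @param calibrated Mark the output as calibrated (samples in uPa).
#' @return An [audio_segment()].
#' @export
make_tone <- function(freq_hz, duration_s, sample_rate = 8000, rms = 1,
                      calibrated = FALSE) {
  t <- seq(0, duration_s - 1 / sample_rate, by = 1 / sample_rate)
  audio_segment(sqrt(2) * rms * sin(2 * pi * freq_hz * t), sample_rate,
                calibrated = calibrated)
}

#' @rdname make_tone
#' @param low_hz,high_hz Band edges of the noise in Hz.
#' @param seed Optional integer seed.
#' @export
make_band_noise <- function(duration_s, low_hz = 100, high_hz = 1600,
                            sample_rate = 8000, rms = 1, calibrated = FALSE,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sample_rate)
  white <- audio_segment(stats::rnorm(n), sample_rate)
  shaped <- bandpass(white, low_hz, high_hz)
  x <- shaped$samples
  x <- x / sqrt(mean(x^2)) * rms
  audio_segment(x, sample_rate, calibrated = calibrated)
}
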