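#' Audio segment
#'
#' A mono pressure waveform with its sample rate. Calibrated segments hold
#' samples in micropascal (uPa), the underwater reference pressure unit;
#' uncalibrated segments are in arbitrary (e.g. full-scale) units.
#'
#' @param samples Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param calibrated Logical; TRUE if samples are in uPa.
#' @return An object of class \code{audio_segment}.
#' @export
audio_segment <- function(samples, sample_rate, calibrated = FALSE) {
  stopifnot(is.numeric(samples), length(samples) >= 1,
            is.numeric(sample_rate), sample_rate > 0)
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 calibrated = isTRUE(calibrated)),
            class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("Audio segment: %.2f s at %g Hz (%s)\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              if (x$calibrated) "calibrated, uPa" else "uncalibrated"))
  invisible(x)
}

#' Duration of an audio segment in seconds
#' @param segment An [audio_segment()].
#' @return Duration in seconds.
#' @export
segment_duration <- function(segment) {
  length(segment$samples) / segment$sample_rate
}

equal_gain_ramp <- function(n) {
  if (n < 2) stop("crossfade must span at least 2 samples")
  seq(1, 0, length.out = n)
}

join_with_crossfade <- function(a, b, n_fade) {
  w <- equal_gain_ramp(n_fade)
  na <- length(a)
  head_a <- a[seq_len(na - n_fade)]
  mix <- a[seq(na - n_fade + 1, na)] * w + b[seq_len(n_fade)] * (1 - w)
  c(head_a, mix, b[-seq_len(n_fade)])
}

#' Loop a segment into a long track with linear crossfades
#'
#' Repeats the segment, joining copies with equal-gain linear crossfades (the
#' outgoing copy fades 1 to 0 while the incoming fades 0 to 1; the gains sum
#' to exactly 1, so looping constant material reproduces it exactly), then
#' trims to the target duration. Default: 25 min tracks with 3 s crossfades,
#' the construction used for playback stimuli.
#'
#' @param segment An [audio_segment()] longer than the crossfade.
#' @param target_duration_s Target track duration in seconds (default 1500).
#' @param crossfade_s Crossfade duration in seconds (default 3).
#' @return An [audio_segment()] of exactly
#'   \code{round(target_duration_s * sample_rate)} samples.
#' @export
loop_with_crossfade <- function(segment, target_duration_s = 1500,
                                crossfade_s = 3) {
  stopifnot(inherits(segment, "audio_segment"))
  fs <- segment$sample_rate
  n_fade <- round(crossfade_s * fs)
  if (length(segment$samples) <= n_fade)
    stop("segment must be longer than the crossfade")
  target_n <- round(target_duration_s * fs)
  out <- segment$samples
  while (length(out) < target_n)
    out <- join_with_crossfade(out, segment$samples, n_fade)
  audio_segment(out[seq_len(target_n)], fs, calibrated = segment$calibrated)
}

#' Crossfade two tracks together
#'
#' Joins two segments with one equal-gain linear crossfade; used to switch
#' from the ambient track to the treatment track (default 10 s fade). The
#' result has \code{length(a) + length(b) - crossfade} samples.
#'
#' @param a,b [audio_segment()] objects at the same sample rate, each longer
#'   than the crossfade.
#' @param crossfade_s Crossfade duration in seconds (default 10).
#' @return An [audio_segment()].
#' @export
crossfade_join <- function(a, b, crossfade_s = 10) {
  stopifnot(inherits(a, "audio_segment"), inherits(b, "audio_segment"))
  if (a$sample_rate != b$sample_rate) stop("sample rates differ")
  n_fade <- round(crossfade_s * a$sample_rate)
  if (length(a$samples) <= n_fade || length(b$samples) <= n_fade)
    stop("both segments must be longer than the crossfade")
  audio_segment(join_with_crossfade(a$samples, b$samples, n_fade),
                a$sample_rate, calibrated = a$calibrated && b$calibrated)
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' (\code{signal::filtfilt}), giving zero phase shift and a squared magnitude
#' response: the passband is maximally flat (ripple well under 1 dB) and
#' attenuation one octave outside the band exceeds 20 dB at the default
#' order. Default band 100--1600 Hz, the stimulus construction band.
#'
#' @param segment An [audio_segment()].
#' @param low_hz,high_hz Band edges in Hz; \code{high_hz} must be below the
#'   Nyquist frequency.
#' @param order Butterworth order per pass (default 4).
#' @return The filtered [audio_segment()].
#' @export
bandpass <- function(segment, low_hz = 100, high_hz = 1600, order = 4) {
  stopifnot(inherits(segment, "audio_segment"))
  nyq <- segment$sample_rate / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq))
    stop("invalid band: need 0 < low < high < Nyquist")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  audio_segment(signal::filtfilt(bf, segment$samples), segment$sample_rate,
                calibrated = segment$calibrated)
}

#' Welch power spectral density
#'
#' Averaged-periodogram (Welch) estimate: the signal is split into
#' windowed segments (Hann window, default length 6144) with 50% overlap,
#' each segment is mean-detrended, and the one-sided periodograms are
#' averaged and normalized to a density (unit^2 per Hz), so the integral of
#' the density over frequency matches the signal variance. For calibrated
#' input the dB column is re 1 uPa^2/Hz.
#'
#' @param segment An [audio_segment()] of at least \code{window_length}
#'   samples.
#' @param window_length Segment/window length in samples (default 6144).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return An object of class \code{spectrum_result}: list with \code{freq}
#'   (Hz), \code{psd} (linear density), \code{psd_db}
#'   (\code{10*log10(psd)}), \code{window_type}, \code{window_length},
#'   \code{overlap}, \code{n_segments}, \code{calibrated}.
#' @export
psd <- function(segment, window_length = 6144, overlap = 0.5) {
  stopifnot(inherits(segment, "audio_segment"))
  x <- segment$samples
  nw <- as.integer(window_length)
  if (length(x) < nw) stop("segment shorter than the analysis window")
  fs <- segment$sample_rate
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / nw))  # periodic Hann
  step <- max(1L, as.integer(round(nw * (1 - overlap))))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  acc <- numeric(nw)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + abs(stats::fft(seg))^2
  }
  pxx <- acc / length(starts) / (fs * sum(w^2))
  half <- seq_len(nw %/% 2 + 1)
  pxx <- pxx[half]
  scale2 <- rep(2, length(half)); scale2[1] <- 1
  if (nw %% 2 == 0) scale2[length(half)] <- 1
  pxx <- pxx * scale2
  structure(
    list(freq = (half - 1) * fs / nw, psd = pxx,
         psd_db = 10 * log10(pmax(pxx, .Machine$double.xmin)),
         window_type = "hann", window_length = nw, overlap = overlap,
         n_segments = length(starts), calibrated = segment$calibrated),
    class = "spectrum_result"
  )
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("Welch PSD: %d bins to %.0f Hz (%s window %d, %d segments)\n",
              length(x$freq), max(x$freq), x$window_type, x$window_length,
              x$n_segments))
  invisible(x)
}

#' Band rms sound pressure level
#'
#' Band-pass filters a calibrated segment (default 100--600 Hz) and reports
#' \code{20 log10(rms / 1 uPa)}, the rms SPL in dB re 1 uPa. A settling
#' margin (default 5 low-band periods each end) is discarded before the rms
#' to exclude zero-phase filter edge transients.
#'
#' @param segment A calibrated [audio_segment()] (samples in uPa).
#' @param band Length-2 numeric band in Hz (default \code{c(100, 600)}).
#' @param order Filter order, see [bandpass()].
#' @param settle_periods Number of low-edge periods trimmed from each end
#'   before the rms.
#' @return One-row data frame: \code{band_low_hz}, \code{band_high_hz},
#'   \code{spl_db} (dB re 1 uPa).
#' @examples
#' fs <- 4000; t <- seq(0, 20, by = 1 / fs)
#' tone <- audio_segment(sqrt(2) * 1e6 * sin(2 * pi * 300 * t), fs,
#'                       calibrated = TRUE)
#' band_rms_spl(tone)$spl_db  # 120 dB re 1 uPa
#' @export
band_rms_spl <- function(segment, band = c(100, 600), order = 4,
                         settle_periods = 5) {
  stopifnot(inherits(segment, "audio_segment"))
  if (!segment$calibrated)
    stop("band_rms_spl requires a calibrated segment (samples in uPa)")
  filt <- bandpass(segment, band[1], band[2], order = order)
  x <- filt$samples
  margin <- min(floor(settle_periods / band[1] * segment$sample_rate),
                floor((length(x) - 2) / 2))
  if (margin > 0) x <- x[(margin + 1):(length(x) - margin)]
  rms <- sqrt(mean(x^2))
  data.frame(band_low_hz = band[1], band_high_hz = band[2],
             spl_db = 20 * log10(rms / 1))
}

#' Aggregate SPL values across measurement locations
#'
#' Arithmetic mean in the dB domain, i.e. the geometric mean of the
#' underlying pressure ratios -- the convention for summarizing SPL measured
#' at several locations.
#'
#' @param spl_db Numeric vector of SPL values in dB (at least one).
#' @return Aggregated SPL in dB.
#' @examples
#' aggregate_spl(c(100, 120, 140))  # 120
#' @export
aggregate_spl <- function(spl_db) {
  if (!length(spl_db)) stop("need at least one SPL value")
  if (any(!is.finite(spl_db))) stop("SPL values must be finite")
  mean(spl_db)
}
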