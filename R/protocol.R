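#' Trial protocol: phase timeline and analysis windows
#'
#' Describes the timeline of a single exposure trial: three contiguous
#' playback phases (silence, ambient, treatment), the time at which the
#' predator (crab) is introduced, the time of the switch to the treatment
#' sound, and the logger sampling interval.
#'
#' The default protocol is a 75 min trial: 25 min silence, 25 min ambient
#' playback, 25 min treatment playback (either boat noise or a second
#' ambient track), with the crab introduced 45 min after the start
#' (5 min before the sound switch) and a nominal sampling rate of
#' about 47.3 points per minute (one sample every 1.27 s).
#'
#' All analysis windows derived from a protocol are half-open
#' \code{[start, end)} in seconds from trial start.
#'
#' @param total_duration_s Total trial duration in seconds.
#' @param phase_boundaries_s Numeric vector of length 2 with the internal
#'   phase boundaries (end of silence, end of ambient) in seconds.
#' @param crab_intro_s Time of crab introduction in seconds.
#' @param sound_switch_s Time of the switch to the treatment sound in seconds.
#' @param sample_interval_s Logger sampling interval in seconds.
#' @return An object of class \code{trial_protocol}: a list with fields
#'   \code{total_duration_s}, \code{phases} (data frame with columns
#'   \code{label}, \code{start_s}, \code{end_s}), \code{crab_intro_s},
#'   \code{sound_switch_s} and \code{sample_interval_s}.
#' @examples
#' p <- trial_protocol()
#' p$phases
#' @export
trial_protocol <- function(total_duration_s = 4500,
                           phase_boundaries_s = c(1500, 3000),
                           crab_intro_s = 2700,
                           sound_switch_s = 3000,
                           sample_interval_s = 1.27) {
  stopifnot(is.numeric(total_duration_s), length(total_duration_s) == 1,
            total_duration_s > 0,
            is.numeric(phase_boundaries_s), length(phase_boundaries_s) == 2,
            is.numeric(sample_interval_s), sample_interval_s > 0)
  b <- phase_boundaries_s
  if (!(0 < b[1] && b[1] < b[2] && b[2] <= total_duration_s))
    stop("phase boundaries must satisfy 0 < b1 < b2 <= total_duration_s")
  if (!(crab_intro_s < sound_switch_s && sound_switch_s < total_duration_s))
    stop("protocol requires crab_intro_s < sound_switch_s < total_duration_s")
  phases <- data.frame(
    label   = c("silence", "ambient", "treatment"),
    start_s = c(0, b[1], b[2]),
    end_s   = c(b[1], b[2], total_duration_s),
    stringsAsFactors = FALSE
  )
  structure(
    list(total_duration_s = total_duration_s,
         phases = phases,
         crab_intro_s = crab_intro_s,
         sound_switch_s = sound_switch_s,
         sample_interval_s = sample_interval_s),
    class = "trial_protocol"
  )
}

#' @export
print.trial_protocol <- function(x, ...) {
  cat(sprintf("Trial protocol: %.0f s total, crab at %.0f s, sound switch at %.0f s, dt = %.3g s\n",
              x$total_duration_s, x$crab_intro_s, x$sound_switch_s,
              x$sample_interval_s))
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' Sampling grid of a protocol
#'
#' Sample times in seconds from trial start: \code{0, dt, 2 dt, ...}, strictly
#' below the total duration.
#'
#' @param protocol A [trial_protocol()].
#' @return Numeric vector of sample times.
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "trial_protocol"))
  dt <- protocol$sample_interval_s
  seq(0, protocol$total_duration_s - 1e-9, by = dt)
}

#' Analysis windows derived from a protocol
#'
#' Returns the standard half-open analysis windows, in seconds:
#' \describe{
#'   \item{short_pre / short_post}{30 s either side of the sound switch,
#'     for the short-term gape response.}
#'   \item{long_baseline}{from 5 min to 1 min before crab introduction
#'     (min 40--44 under the default protocol).}
#'   \item{long_treatment}{the whole treatment phase (min 50--75).}
#'   \item{event_baseline}{from 20.5 min to 1 min before crab introduction,
#'     for the baseline closing-event rate.}
#'   \item{event_treatment}{treatment phase with a 30 s margin after the
#'     switch, so onset-driven closures are not counted.}
#' }
#'
#' @param protocol A [trial_protocol()].
#' @return Named list of length-2 numeric vectors \code{c(start_s, end_s)}.
#' @export
analysis_windows <- function(protocol) {
  stopifnot(inherits(protocol, "trial_protocol"))
  sw <- protocol$sound_switch_s
  ci <- protocol$crab_intro_s
  list(
    short_pre       = c(sw - 30, sw),
    short_post      = c(sw, sw + 30),
    long_baseline   = c(ci - 300, ci - 60),
    long_treatment  = c(sw, protocol$total_duration_s),
    event_baseline  = c(20.5 * 60, ci - 60),
    event_treatment = c(sw + 30, protocol$total_duration_s)
  )
}
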