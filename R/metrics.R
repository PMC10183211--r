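#' Mean gape over a half-open time window
#'
#' Unweighted arithmetic mean of the samples with \code{start_s <= t < end_s}.
#' Sampling is near-uniform, so unweighted means are used by default; a
#' time-weighted trapezoid alternative is available.
#'
#' @param trace A [gape_trace()].
#' @param start_s,end_s Window bounds in seconds, half-open.
#' @param weighted Use trapezoidal time weighting instead of the sample mean.
#' @return The mean fraction open (or mm) over the window.
#' @export
epoch_mean <- function(trace, start_s, end_s, weighted = FALSE) {
  if (!inherits(trace, "gape_trace")) stop("trace must be a gape_trace")
  if (start_s >= end_s) stop("window must satisfy start_s < end_s")
  inside <- trace$time_s >= start_s & trace$time_s < end_s
  if (!any(inside)) stop("no data in the requested window")
  if (!weighted) return(mean(trace$value[inside]))
  tt <- trace$time_s[inside]; v <- trace$value[inside]
  if (length(tt) < 2) return(mean(v))
  sum(diff(tt) * (v[-1] + v[-length(v)]) / 2) / (tt[length(tt)] - tt[1])
}

#' Short-term gape response at the sound switch
#'
#' Difference in mean fraction open between the 30 s after and the 30 s
#' before the switch to the treatment sound; negative values are a closing
#' response. Optionally the post window is shifted by the 10 s crossfade so
#' only the fully switched stimulus is scored.
#'
#' @param trace A fraction-open [gape_trace()] covering both windows.
#' @param protocol A [trial_protocol()].
#' @param skip_crossfade_s Shift of the post-switch window in seconds
#'   (default 0: the crossfade is included).
#' @return Delta fraction open (post minus pre), in [-1, 1].
#' @export
short_term_response <- function(trace, protocol, skip_crossfade_s = 0) {
  w <- analysis_windows(protocol)
  post <- w$short_post + skip_crossfade_s
  epoch_mean(trace, post[1], post[2]) -
    epoch_mean(trace, w$short_pre[1], w$short_pre[2])
}

#' Long-term gape response to the treatment
#'
#' Difference between the mean fraction open over the whole treatment phase
#' (min 50--75 under the default protocol) and a baseline window shortly
#' before crab introduction (min 40--44). Using a within-individual baseline
#' removes inter-individual differences in resting gape.
#'
#' @inheritParams short_term_response
#' @return Delta fraction open (treatment minus baseline), in [-1, 1].
#' @export
long_term_response <- function(trace, protocol) {
  w <- analysis_windows(protocol)
  epoch_mean(trace, w$long_treatment[1], w$long_treatment[2]) -
    epoch_mean(trace, w$long_baseline[1], w$long_baseline[2])
}

#' Per-mussel metrics table for the statistical models
#'
#' Runs the processing pipeline over a set of simulated (or imported) trials:
#' normalizes each mm gape trace to fraction open, computes the short- and
#' long-term responses, detects strong closing events and their rate change,
#' and, for crab-in-tank records with a scored track, the ethogram time
#' budget over the scoring window.
#'
#' @param trials List of \code{simulated_trial} objects
#'   ([simulate_experiment()] output) or a list with fields \code{gape_raw}
#'   (mm [gape_trace()]), \code{metadata} and optional \code{crab_track}.
#' @param protocol A [trial_protocol()].
#' @param detect Compute closing events and \code{delta_event_rate}
#'   (default TRUE; skipping saves time when only gape deltas are needed).
#' @param window,multiplier Detector settings, see [detect_events()].
#' @param scoring_window Ethogram scoring window; default the last 25 min of
#'   the trial.
#' @return Data frame with one row per mussel: \code{trial_id},
#'   \code{mussel_id}, \code{treatment}, \code{crab_condition},
#'   \code{mussel_size}, \code{crab_size}, \code{short_term_delta},
#'   \code{long_term_delta}, \code{delta_event_rate} (NA when
#'   \code{detect = FALSE}), \code{close_or_touching} (NA outside
#'   crab-in-tank), \code{touching_s}.
#' @export
trial_metrics <- function(trials, protocol = trial_protocol(), detect = TRUE,
                          window = 15, multiplier = -15,
                          scoring_window = NULL) {
  if (is.null(scoring_window))
    scoring_window <- c(protocol$total_duration_s - 1500,
                        protocol$total_duration_s)
  n <- length(trials)
  trial_id <- mussel_id <- treatment <- crab_condition <- character(n)
  mussel_size <- crab_size <- short_d <- long_d <- der <- cot <- numeric(n)
  touch_s <- integer(n)
  for (i in seq_len(n)) {
    tr <- trials[[i]]
    md <- tr$metadata
    frac <- normalize_fraction_open(tr$gape_raw)
    der[i] <- NA_real_
    if (detect) {
      ev <- suppressWarnings(detect_events(frac, window = window,
                                           multiplier = multiplier))
      der[i] <- event_rate_change(ev, protocol)$delta_rate
    }
    cot[i] <- NA_real_; touch_s[i] <- NA_integer_
    if (!is.null(tr$crab_track)) {
      b <- time_budget(tr$crab_track, window = scoring_window)
      cot[i] <- b$fraction_close_or_touching
      touch_s[i] <- as.integer(round(b$fraction_touching *
                                       (scoring_window[2] - scoring_window[1])))
    }
    trial_id[i] <- md$trial_id; mussel_id[i] <- md$mussel_id
    treatment[i] <- md$treatment; crab_condition[i] <- md$crab_condition
    mussel_size[i] <- md$mussel_size; crab_size[i] <- md$crab_size
    short_d[i] <- short_term_response(frac, protocol)
    long_d[i] <- long_term_response(frac, protocol)
  }
  out <- data.frame(trial_id = trial_id, mussel_id = mussel_id,
                    treatment = treatment, crab_condition = crab_condition,
                    mussel_size = mussel_size, crab_size = crab_size,
                    short_term_delta = short_d, long_term_delta = long_d,
                    delta_event_rate = der, close_or_touching = cot,
                    touching_s = touch_s, stringsAsFactors = FALSE)
  out$treatment <- factor(out$treatment, levels = c("ambient", "boat"))
  out$crab_condition <- factor(out$crab_condition,
                               levels = c("no_crab", "crab_in_box", "crab_in_tank"))
  out
}
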