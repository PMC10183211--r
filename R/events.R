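#' Centered moving average of a gape trace
#'
#' Simple moving average over an odd window of samples. The output is defined
#' only where the full window fits, so the first and last
#' \code{(window - 1) / 2} samples are dropped. A trailing alignment is
#' available for streaming use.
#'
#' @param trace A [gape_trace()].
#' @param window Odd positive integer window length in samples (default 15).
#' @param align \code{"center"} (default) or \code{"trailing"}.
#' @return A [gape_trace()] of length \code{length(trace) - window + 1}.
#' @export
moving_average <- function(trace, window = 15, align = c("center", "trailing")) {
  align <- match.arg(align)
  stopifnot(inherits(trace, "gape_trace"))
  if (window < 1 || window %% 2 != 1 || window != round(window))
    stop("window must be an odd positive integer")
  n <- length(trace$time_s)
  if (n < window) stop("insufficient data: trace shorter than the window")
  ma <- as.numeric(stats::filter(trace$value, rep(1 / window, window),
                                 sides = 2))
  half <- (window - 1) / 2
  keep <- seq(half + 1, n - half)
  tt <- if (align == "center") trace$time_s[keep]
        else trace$time_s[seq(window, n)]
  new_gape_trace(tt, ma[keep], unit = trace$unit, mussel_id = trace$mussel_id)
}

#' First differences of a moving-averaged trace
#'
#' The difference of sequential moving-average values; large negative values
#' mark rapid valve closures. Each difference is timestamped at the later
#' point of its pair.
#'
#' @param ma A [gape_trace()] (usually the output of [moving_average()]).
#' @return Data frame with columns \code{time_s} and \code{dma}, of length
#'   \code{length(ma) - 1}.
#' @export
delta_ma <- function(ma) {
  stopifnot(inherits(ma, "gape_trace"))
  if (length(ma$time_s) < 2) stop("need at least 2 moving-average points")
  data.frame(time_s = ma$time_s[-1], dma = diff(ma$value))
}

#' Robust closing-event threshold
#'
#' Threshold for strong closing events: \code{multiplier} times the sample
#' standard deviation of the central 50% of the difference series -- the
#' values lying between its 25th and 75th percentiles (inclusive,
#' linear-interpolation quantiles). The interquartile restriction makes the
#' spread estimate insensitive to the closures themselves. An alternative
#' reading, the 50% of values nearest the median by rank, is selectable.
#'
#' If the central subset has zero spread the threshold is 0 and flagged
#' degenerate; no events will be reported from such a trace.
#'
#' @param dma Numeric vector of moving-average differences (or the data frame
#'   from [delta_ma()]).
#' @param multiplier Threshold multiplier, default -15.
#' @param central \code{"iqr"} (default) or \code{"rank"}.
#' @return Numeric threshold (<= 0 for negative multipliers) with attributes
#'   \code{degenerate} (logical) and \code{central_sd}.
#' @examples
#' robust_threshold(c(-2, -1, 0, 1, 2))  # -15
#' @export
robust_threshold <- function(dma, multiplier = -15, central = c("iqr", "rank")) {
  central <- match.arg(central)
  if (is.data.frame(dma)) dma <- dma$dma
  if (length(dma) < 4) stop("need at least 4 difference values")
  if (central == "iqr") {
    q <- stats::quantile(dma, c(0.25, 0.75), names = FALSE, type = 7)
    sub <- dma[dma >= q[1] & dma <= q[2]]
  } else {
    o <- order(abs(dma - stats::median(dma)))
    sub <- dma[o[seq_len(ceiling(length(dma) / 2))]]
  }
  s <- stats::sd(sub)
  degen <- !is.finite(s) || s <= 0
  thr <- if (degen) 0 else multiplier * s
  structure(thr, degenerate = degen, central_sd = if (degen) 0 else s)
}

#' Detect sudden strong valve-closing events
#'
#' Full detector pipeline: moving average, sequential differences, robust
#' threshold, then event extraction. An event is each maximal run of
#' consecutive difference values below the threshold, reported at the run's
#' first timestamp, so a single multi-sample closure counts once. The
#' threshold is computed over the whole trace's difference series (one
#' threshold per individual).
#'
#' @param trace A [gape_trace()] in fraction-open units.
#' @param window Moving-average window in samples (default 15).
#' @param multiplier Threshold multiplier (default -15).
#' @param align Moving-average alignment, see [moving_average()].
#' @param central Central-subset rule, see [robust_threshold()].
#' @return An object of class \code{closing_events}: list with
#'   \code{event_times_s}, \code{event_dma} (the most negative difference in
#'   each run), \code{threshold}, \code{window}, \code{multiplier},
#'   \code{degenerate}, \code{trace_id}.
#' @export
detect_events <- function(trace, window = 15, multiplier = -15,
                          align = "center", central = "iqr") {
  ma <- moving_average(trace, window = window, align = align)
  d <- delta_ma(ma)
  thr <- robust_threshold(d$dma, multiplier = multiplier, central = central)
  if (attr(thr, "degenerate")) {
    warning("degenerate threshold (no spread in the central differences); no events reported",
            call. = FALSE)
    below <- rep(FALSE, length(d$dma))
  } else {
    below <- d$dma < as.numeric(thr)
  }
  starts <- which(below & !c(FALSE, below[-length(below)]))
  ends <- which(below & !c(below[-1], FALSE))
  ev_dma <- if (length(starts))
    vapply(seq_along(starts),
           function(i) min(d$dma[starts[i]:ends[i]]), numeric(1))
    else numeric(0)
  structure(
    list(event_times_s = d$time_s[starts],
         event_dma = ev_dma,
         threshold = as.numeric(thr),
         window = window, multiplier = multiplier,
         degenerate = attr(thr, "degenerate"),
         trace_id = trace$mussel_id),
    class = "closing_events"
  )
}

#' @export
print.closing_events <- function(x, ...) {
  cat(sprintf("%d strong closing events (threshold %.3g, window %d) for %s\n",
              length(x$event_times_s), x$threshold, x$window, x$trace_id))
  invisible(x)
}

#' Change in strong-closing-event rate between analysis windows
#'
#' Compares the event rate (events per 10 min) in the baseline window before
#' crab introduction with the rate during the treatment sound. Default
#' windows come from [analysis_windows()]: baseline 20.5 min to 1 min before
#' crab introduction, treatment from 30 s after the sound switch to the end
#' of the trial.
#'
#' @param events A [detect_events()] result.
#' @param protocol A [trial_protocol()].
#' @param baseline_window,treatment_window Optional explicit windows
#'   \code{c(start_s, end_s)}, half-open.
#' @return One-row data frame: \code{baseline_rate}, \code{treatment_rate},
#'   \code{delta_rate} (all events per 10 min), \code{baseline_count},
#'   \code{treatment_count}.
#' @export
event_rate_change <- function(events, protocol,
                              baseline_window = NULL, treatment_window = NULL) {
  stopifnot(inherits(events, "closing_events"))
  w <- analysis_windows(protocol)
  if (is.null(baseline_window)) baseline_window <- w$event_baseline
  if (is.null(treatment_window)) treatment_window <- w$event_treatment
  rate <- function(win) {
    k <- sum(events$event_times_s >= win[1] & events$event_times_s < win[2])
    c(k, k / ((win[2] - win[1]) / 60 / 10))
  }
  b <- rate(baseline_window); tr <- rate(treatment_window)
  data.frame(baseline_rate = b[2], treatment_rate = tr[2],
             delta_rate = tr[2] - b[2],
             baseline_count = b[1], treatment_count = tr[1])
}

#' Write detected events as CSV
#'
#' Columns: \code{trace_id}, \code{event_time_s}, \code{dma_value},
#' \code{threshold}.
#'
#' @param events_list List of [detect_events()] results.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events_list, path) {
  rows <- do.call(rbind, lapply(events_list, function(e) {
    if (!length(e$event_times_s)) return(NULL)
    data.frame(trace_id = e$trace_id, event_time_s = e$event_times_s,
               dma_value = e$event_dma, threshold = e$threshold,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(trace_id = character(), event_time_s = numeric(),
                       dma_value = numeric(), threshold = numeric())
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
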