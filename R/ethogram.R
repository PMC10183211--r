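#' Crab state track
#'
#' An ordered sequence of behavioural state transitions for the stimulus crab
#' over the alphabet \code{away} (under its box, far from the mussel),
#' \code{close} (out in the tank, near the mussel) and \code{touching}.
#' The first transition marks the state at the start of the scoring window;
#' the last state persists to the window end.
#'
#' @param time_s Strictly increasing transition times in seconds; the first
#'   must equal \code{window[1]}.
#' @param state Character vector of states, same length as \code{time_s}.
#' @param window Length-2 numeric, the scoring window \code{[start, end)}.
#' @return An object of class \code{crab_track}.
#' @examples
#' tr <- crab_track(c(0, 600, 1200), c("away", "close", "touching"),
#'                  window = c(0, 1500))
#' time_budget(tr)
#' @export
crab_track <- function(time_s, state, window) {
  stopifnot(length(time_s) == length(state), length(time_s) >= 1,
            length(window) == 2, window[1] < window[2])
  state <- as.character(state)
  viol <- track_violations(time_s, state, window)
  if (length(viol$errors)) stop(paste(viol$errors, collapse = "; "))
  if (length(viol$warnings)) for (w in viol$warnings) warning(w, call. = FALSE)
  keep <- c(TRUE, state[-1] != state[-length(state)])  # collapse self-transitions
  structure(
    list(transitions = data.frame(time_s = time_s[keep], state = state[keep],
                                  stringsAsFactors = FALSE),
         window = as.numeric(window)),
    class = "crab_track"
  )
}

track_violations <- function(time_s, state, window) {
  errors <- character(); warnings <- character()
  if (any(diff(time_s) <= 0))
    errors <- c(errors, "transition times must be strictly increasing")
  if (!all(state %in% crab_states()))
    errors <- c(errors, sprintf("unknown state labels: %s",
                                paste(unique(setdiff(state, crab_states())), collapse = ", ")))
  if (abs(time_s[1] - window[1]) > 1e-9)
    errors <- c(errors, "first transition must be at the window start")
  if (any(time_s < window[1] - 1e-9) || any(time_s >= window[2]))
    errors <- c(errors, "transitions outside the scoring window")
  if (any(state[-1] == state[-length(state)]))
    warnings <- c(warnings, "consecutive repeats of the same state collapsed")
  list(errors = errors, warnings = warnings)
}

#' Validate a raw transition log
#'
#' Reports structural problems in a scored transition log without
#' constructing a track: non-monotone timestamps, unknown state labels,
#' consecutive self-transitions (these are collapsed by [crab_track()] with a
#' warning), and transitions outside the scoring window.
#'
#' @inheritParams crab_track
#' @return Character vector of violation messages (empty if well formed).
#' @export
validate_track <- function(time_s, state, window) {
  v <- track_violations(time_s, as.character(state), window)
  c(v$errors, v$warnings)
}

#' @export
print.crab_track <- function(x, ...) {
  cat(sprintf("Crab track over [%.1f, %.1f) s, %d transitions\n",
              x$window[1], x$window[2], nrow(x$transitions)))
  invisible(x)
}

#' Restrict a crab track to a sub-window
#'
#' Clips a track to \code{[start, end)}; the state at the new window start is
#' the state active at that time in the original track.
#'
#' @param track A [crab_track()].
#' @param window Length-2 numeric sub-window, contained in the track window.
#' @return A [crab_track()] over the sub-window.
#' @export
clip_track <- function(track, window) {
  stopifnot(inherits(track, "crab_track"), length(window) == 2)
  if (window[1] < track$window[1] - 1e-9 || window[2] > track$window[2] + 1e-9)
    stop("clip window must lie within the track window")
  tr <- track$transitions
  at_start <- tr$state[max(which(tr$time_s <= window[1] + 1e-12))]
  inside <- tr$time_s > window[1] & tr$time_s < window[2]
  crab_track(c(window[1], tr$time_s[inside]),
             c(at_start, tr$state[inside]),
             window = window)
}

#' Ethogram time budget
#'
#' Fraction of the scoring window spent in each behavioural state, plus the
#' combined fraction close-or-touching used as the predator-proximity
#' covariate for the gape analysis.
#'
#' @param track A [crab_track()].
#' @param window Optional sub-window; defaults to the track's own window.
#' @return A one-row data frame with columns \code{fraction_away},
#'   \code{fraction_close}, \code{fraction_touching},
#'   \code{fraction_close_or_touching}, \code{window_start_s},
#'   \code{window_end_s}.
#' @examples
#' tr <- crab_track(c(0, 600, 1200), c("away", "close", "touching"), c(0, 1500))
#' time_budget(tr)  # 0.4, 0.4, 0.2
#' @export
time_budget <- function(track, window = NULL) {
  stopifnot(inherits(track, "crab_track"))
  if (!is.null(window)) track <- clip_track(track, window)
  tr <- track$transitions
  w <- track$window
  len <- w[2] - w[1]
  ends <- c(tr$time_s[-1], w[2])
  occ <- vapply(crab_states(),
                function(s) sum((ends - tr$time_s)[tr$state == s]), numeric(1))
  f <- occ / len
  data.frame(fraction_away = f[["away"]],
             fraction_close = f[["close"]],
             fraction_touching = f[["touching"]],
             fraction_close_or_touching = f[["close"]] + f[["touching"]],
             window_start_s = w[1], window_end_s = w[2])
}

#' Seconds spent touching, as an integer count
#'
#' Integer seconds of the scoring window spent in the \code{touching} state,
#' the count response used for the Poisson model of crab contact time.
#'
#' @inheritParams time_budget
#' @return Integer number of whole seconds (rounded).
#' @export
touching_seconds <- function(track, window = NULL) {
  b <- time_budget(track, window)
  as.integer(round(b$fraction_touching * (b$window_end_s - b$window_start_s)))
}

#' Read / write crab transition logs
#'
#' CSV dialect: columns \code{trial_id}, \code{time_s}, \code{state}.
#'
#' @param tracks Named list of [crab_track()] objects (names = trial ids).
#' @param path CSV file path.
#' @return `write_crab_csv()` returns `path` invisibly; `read_crab_csv()`
#'   returns a named list of tracks (the scoring window is taken as
#'   \code{[first transition, window_end_s)} passed by the caller).
#' @param window_end_s End of the scoring window for all tracks in the file.
#' @export
write_crab_csv <- function(tracks, path) {
  rows <- do.call(rbind, lapply(names(tracks), function(id) {
    tr <- tracks[[id]]$transitions
    data.frame(trial_id = id, time_s = tr$time_s, state = tr$state,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_crab_csv
#' @export
read_crab_csv <- function(path, window_end_s) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial_id", "time_s", "state") %in% names(x)))
  out <- lapply(split(x, x$trial_id), function(d) {
    d <- d[order(d$time_s), ]
    crab_track(d$time_s, d$state, window = c(d$time_s[1], window_end_s))
  })
  out
}
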