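#' Valve-gape trace
#'
#' A timestamped valve-opening series for one mussel, either calibrated
#' distances in mm or a normalized fraction-open series in [0, 1].
#'
#' @param time_s Strictly increasing sample times, seconds from trial start.
#' @param value Gape values (mm or fraction open).
#' @param unit Either \code{"mm"} or \code{"fraction"}.
#' @param mussel_id Identifier carried through the pipeline.
#' @return An object of class \code{gape_trace}.
#' @export
gape_trace <- function(time_s, value, unit = c("mm", "fraction"),
                       mussel_id = NA_character_) {
  if (length(unit) > 1) unit <- unit[1]
  if (!unit %in% c("mm", "fraction")) stop("unit must be 'mm' or 'fraction'")
  n <- length(time_s)
  if (n < 1 || length(value) != n)
    stop("time_s and value must have equal positive length")
  if (anyNA(time_s) || anyNA(value) ||
      !all(is.finite(range(time_s))) || !all(is.finite(range(value))))
    stop("gape trace must be finite")
  if (n > 1 && any(diff(time_s) <= 0))
    stop("gape trace timestamps must be strictly increasing")
  if (unit == "mm" && min(value) < 0) stop("mm gape values must be nonnegative")
  new_gape_trace(time_s, value, unit, mussel_id)
}

# internal constructor for vectors already known to be valid
new_gape_trace <- function(time_s, value, unit, mussel_id) {
  structure(list(time_s = as.numeric(time_s), value = as.numeric(value),
                 unit = unit, mussel_id = mussel_id),
            class = "gape_trace")
}

#' @export
print.gape_trace <- function(x, ...) {
  cat(sprintf("Gape trace %s: %d samples over [%.1f, %.1f] s (%s)\n",
              x$mussel_id, length(x$time_s), x$time_s[1],
              x$time_s[length(x$time_s)], x$unit))
  invisible(x)
}

#' @export
length.gape_trace <- function(x) length(x$time_s)

#' Sensor calibration model
#'
#' Ordered pairs mapping raw electromagnetic field strength (arbitrary units)
#' to coil distance (mm). The mapping must be strictly monotone; calibration
#' is applied by monotone piecewise-linear interpolation, reproducing the
#' knots exactly.
#'
#' @param field_strength Raw sensor readings at the calibration knots.
#' @param distance_mm Known distances at those readings.
#' @return An object of class \code{calibration_model}.
#' @examples
#' cal <- calibration_model(c(0, 10), c(0, 5))
#' calibrate(gape_trace(0:2, c(0, 5, 10), "mm"), cal)$value  # interpolated
#' @export
calibration_model <- function(field_strength, distance_mm) {
  stopifnot(length(field_strength) == length(distance_mm))
  if (length(field_strength) < 2) stop("calibration needs at least 2 pairs")
  o <- order(field_strength)
  fs <- field_strength[o]; d <- distance_mm[o]
  if (any(diff(fs) <= 0)) stop("invalid calibration: duplicated field strengths")
  dd <- diff(d)
  if (!(all(dd > 0) || all(dd < 0)))
    stop("invalid calibration: distance must be strictly monotone in field strength")
  structure(list(field_strength = fs, distance_mm = d),
            class = "calibration_model")
}

#' Calibrate raw sensor readings to distances
#'
#' Applies the calibration's monotone piecewise-linear mapping pointwise,
#' preserving timestamps. Readings outside the calibration hull raise an
#' error by default, or are clamped to the nearest knot with a warning.
#'
#' @param raw A [gape_trace()] whose values are raw field-strength readings
#'   (the \code{unit} field is ignored on input), or a data frame with
#'   columns \code{time_s} and \code{field_strength}.
#' @param cal A [calibration_model()].
#' @param out_of_hull \code{"error"} (default) or \code{"clamp"}.
#' @return A [gape_trace()] in mm.
#' @export
calibrate <- function(raw, cal, out_of_hull = c("error", "clamp")) {
  out_of_hull <- match.arg(out_of_hull)
  stopifnot(inherits(cal, "calibration_model"))
  if (is.data.frame(raw)) {
    stopifnot(all(c("time_s", "field_strength") %in% names(raw)))
    id <- if ("mussel_id" %in% names(raw)) raw$mussel_id[1] else NA_character_
    time_s <- raw$time_s; fs <- raw$field_strength
  } else {
    stopifnot(inherits(raw, "gape_trace"))
    id <- raw$mussel_id; time_s <- raw$time_s; fs <- raw$value
  }
  if (any(!is.finite(fs))) stop("raw readings must be finite")
  if (any(diff(time_s) <= 0)) stop("raw timestamps must be strictly increasing")
  rng <- range(cal$field_strength)
  outside <- fs < rng[1] | fs > rng[2]
  if (any(outside)) {
    if (out_of_hull == "error")
      stop(sprintf("%d readings outside the calibration hull [%g, %g]",
                   sum(outside), rng[1], rng[2]))
    warning(sprintf("%d readings clamped to the calibration hull", sum(outside)),
            call. = FALSE)
    fs <- pmin(pmax(fs, rng[1]), rng[2])
  }
  d <- stats::approx(cal$field_strength, cal$distance_mm, xout = fs,
                     method = "linear", ties = "ordered")$y
  gape_trace(time_s, d, unit = "mm", mussel_id = id)
}

#' Normalize a gape trace to fraction open
#'
#' Per-individual min-max normalization: the minimum distance of the trace is
#' subtracted (taken as the fully closed position at the sensor location) and
#' the result is divided by that individual's maximum valve gape, so the
#' output attains 0 and 1 exactly. This removes inter-individual variation in
#' size and sensor placement.
#'
#' @param trace A [gape_trace()] in mm with at least 2 samples.
#' @return A [gape_trace()] in fraction-open units.
#' @export
normalize_fraction_open <- function(trace) {
  stopifnot(inherits(trace, "gape_trace"))
  if (length(trace$time_s) < 2) stop("need at least 2 samples to normalize")
  lo <- min(trace$value); hi <- max(trace$value)
  if (hi - lo <= 0)
    stop("degenerate trace: constant gape, cannot normalize (animal never moved)")
  new_gape_trace(trace$time_s, (trace$value - lo) / (hi - lo),
                 unit = "fraction", mussel_id = trace$mussel_id)
}

#' Exclude invalid traces
#'
#' Filters a set of traces by quality flags: a sensor-dropout fraction
#' threshold (fraction of samples missing relative to the expected protocol
#' grid) and/or an explicit exclusion list (e.g. crab escapees). Returns the
#' retained traces and a structured log of every exclusion with its reason.
#'
#' @param traces Named list of [gape_trace()] objects.
#' @param exclude_ids Character vector of trace names to drop, with optional
#'   names giving the reason (default reason \code{"manual"}).
#' @param max_dropout_fraction Traces whose sample count falls short of
#'   \code{expected_n} by more than this fraction are dropped as sensor
#'   failures. \code{NULL} disables the check.
#' @param expected_n Expected number of samples per trace (e.g.
#'   \code{length(protocol_times(protocol))}).
#' @return List with \code{retained} (named list of traces) and
#'   \code{exclusions} (data frame \code{trace_id}, \code{reason}).
#' @export
exclude_invalid <- function(traces, exclude_ids = character(),
                            max_dropout_fraction = NULL, expected_n = NULL) {
  stopifnot(is.list(traces))
  ids <- names(traces)
  if (is.null(ids)) stop("traces must be a named list")
  reasons <- character(0); dropped <- character(0)
  if (length(exclude_ids)) {
    rs <- names(exclude_ids)
    if (is.null(rs)) rs <- rep("manual", length(exclude_ids))
    rs[rs == ""] <- "manual"
    keep <- exclude_ids %in% ids
    dropped <- c(dropped, unname(exclude_ids[keep]))
    reasons <- c(reasons, rs[keep])
  }
  if (!is.null(max_dropout_fraction)) {
    if (is.null(expected_n)) stop("expected_n required with max_dropout_fraction")
    for (id in setdiff(ids, dropped)) {
      miss <- 1 - length(traces[[id]]$time_s) / expected_n
      if (miss > max_dropout_fraction) {
        dropped <- c(dropped, id)
        reasons <- c(reasons, sprintf("sensor dropout %.1f%%", 100 * miss))
      }
    }
  }
  list(retained = traces[setdiff(ids, dropped)],
       exclusions = data.frame(trace_id = dropped, reason = reasons,
                               stringsAsFactors = FALSE))
}

#' Read / write gape logger CSV files
#'
#' CSV dialect: columns \code{trial_id}, \code{mussel_id}, \code{time_s},
#' \code{field_strength_au}, \code{distance_mm}.
#'
#' @param trials List of simulated trials (see [simulate_experiment()]) or a
#'   data frame already in the dialect.
#' @param path CSV file path.
#' @return `write_gape_csv()` returns `path` invisibly. `read_gape_csv()`
#'   returns a named list of mm [gape_trace()] objects keyed by mussel id,
#'   with a \code{meta} attribute mapping mussel ids to trial ids.
#' @export
write_gape_csv <- function(trials, path) {
  if (!is.data.frame(trials)) {
    trials <- do.call(rbind, lapply(trials, function(tr) {
      data.frame(trial_id = tr$metadata$trial_id,
                 mussel_id = tr$metadata$mussel_id,
                 time_s = round(tr$gape_raw$time_s, 4),
                 field_strength_au = round(tr$field_strength_au, 6),
                 distance_mm = round(tr$gape_raw$value, 6),
                 stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gape_csv
#' @export
read_gape_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mussel_id", "time_s", "distance_mm") %in% names(x)))
  parts <- split(x, x$mussel_id)
  out <- lapply(parts, function(d) {
    d <- d[order(d$time_s), ]
    gape_trace(d$time_s, d$distance_mm, unit = "mm", mussel_id = d$mussel_id[1])
  })
  meta <- vapply(parts, function(d)
    if ("trial_id" %in% names(d)) as.character(d$trial_id[1]) else NA_character_,
    character(1))
  attr(out, "meta") <- data.frame(mussel_id = names(out), trial_id = meta,
                                  stringsAsFactors = FALSE)
  out
}
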