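#' Simulate one mussel's valve-gape trace
#'
#' Builds a latent fraction-open path as the sum of a baseline, a mean-zero
#' Ornstein--Uhlenbeck slow fluctuation, a post-handling re-opening ramp,
#' sustained treatment and predator offsets, a proximity shift coupled to the
#' crab track, and injected rapid-closure pulses; clips to [0, 1]; and
#' converts to mm through a per-animal maximum gape. The injected pulse times
#' are recorded as ground truth. A pulse is only injected while the
#' deterministic open level exceeds the drawn closure depth (a closed animal
#' cannot close rapidly), and only on the sampled span.
#'
#' @param params A [sim_params()].
#' @param protocol A [trial_protocol()].
#' @param metadata List with \code{treatment} (\code{"ambient"} or
#'   \code{"boat"}), \code{crab_condition} (\code{"no_crab"},
#'   \code{"crab_in_box"}, \code{"crab_in_tank"}), \code{mussel_size} (cm),
#'   \code{crab_size} (cm), and optional \code{trial_id}, \code{mussel_id}.
#' @param crab_track Optional [crab_track()] driving the proximity term
#'   (crab-in-tank condition only).
#' @param seed Optional integer seed.
#' @return An object of class \code{simulated_trial}: list with
#'   \code{gape_raw} (mm [gape_trace()]), \code{field_strength_au} (synthetic
#'   raw sensor readings), \code{crab_track} (or \code{NULL}),
#'   \code{metadata}, and \code{truth} (injected \code{event_times_s}, the
#'   \code{max_gape_mm} used, and the generating \code{params}).
#' @examples
#' tr <- simulate_gape_trace(sim_params(), trial_protocol(),
#'                           list(treatment = "boat", crab_condition = "no_crab",
#'                                mussel_size = 4, crab_size = 3), seed = 1)
#' range(tr$gape_raw$value)
#' @export
simulate_gape_trace <- function(params, protocol, metadata,
                                crab_track = NULL, seed = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(protocol, "trial_protocol"))
  validate_sim_params(params)
  treatment <- match.arg(metadata$treatment, c("ambient", "boat"))
  condition <- match.arg(metadata$crab_condition,
                         c("no_crab", "crab_in_box", "crab_in_tank"))
  if (!is.null(seed)) set.seed(seed)

  t <- protocol_times(protocol)
  dt <- protocol$sample_interval_s
  if (params$timestamp_jitter) {
    t <- t + stats::runif(length(t), -0.05 * dt, 0.05 * dt)
    t[1] <- max(t[1], 0)
  }
  n <- length(t)
  sw <- protocol$sound_switch_s
  ci <- protocol$crab_intro_s

  # Ornstein-Uhlenbeck fluctuation, exact discretization at the sample grid
  ou <- numeric(n)
  if (params$ou_sigma > 0) {
    a <- exp(-params$ou_theta * dt)
    innov_sd <- params$ou_sigma * sqrt(1 - a^2)
    e <- c(stats::rnorm(1, 0, params$ou_sigma), stats::rnorm(n - 1, 0, innov_sd))
    ou <- as.numeric(stats::filter(e, a, method = "recursive"))
  }

  handling <- if (params$handling_reopen_tau > 0)
    -params$baseline_open_mean * exp(-t / params$handling_reopen_tau)
  else numeric(n)

  treat <- numeric(n)
  if (treatment == "boat") {
    post <- t >= sw
    treat[post] <- params$sustained_boat_effect +
      params$sound_onset_drop * exp(-(t[post] - sw) / params$onset_recovery_tau)
  }

  crab <- numeric(n)
  if (condition == "crab_in_tank") crab[t >= ci] <- params$crab_in_tank_effect

  prox <- numeric(n)
  if (condition == "crab_in_tank" && !is.null(crab_track)) {
    tr <- crab_track$transitions
    idx <- findInterval(t, tr$time_s)
    active <- idx >= 1 & t < crab_track$window[2]
    st <- rep(NA_character_, n)
    st[active] <- tr$state[idx[active]]
    prox[!is.na(st) & st %in% c("close", "touching")] <- params$proximity_effect_slope
  }

  # rapid-closure pulses: Poisson with phase-dependent rate
  rate_pre <- params$event_rate_baseline / 600   # per second
  rate_post <- if (treatment == "boat") params$event_rate_boat / 600 else rate_pre
  # pulses are injected on the sampled span so every truth event is visible
  ev_pre <- poisson_times(rate_pre, 0, sw)
  ev_post <- poisson_times(rate_post, sw, t[n])
  ev <- sort(c(ev_pre, ev_post))
  depths <- stats::runif(length(ev), params$event_depth_range[1],
                         params$event_depth_range[2])
  if (length(ev)) {
    # a (nearly) closed animal cannot close rapidly: keep a pulse only when
    # the deterministic open level at its onset exceeds the drawn depth
    det <- params$baseline_open_mean + handling + treat + crab + prox
    level <- det[pmax(findInterval(ev, t), 1)]
    open_enough <- level >= depths
    ev <- ev[open_enough]; depths <- depths[open_enough]
  }
  if (params$min_event_gap_s > 0 && length(ev) > 1) {
    keep <- rep(TRUE, length(ev)); last <- ev[1]
    for (i in seq_along(ev)[-1]) {
      if (ev[i] - last < params$min_event_gap_s) keep[i] <- FALSE else last <- ev[i]
    }
    ev <- ev[keep]; depths <- depths[keep]
  }
  pulses <- numeric(n)
  for (i in seq_along(ev)) {
    j <- t >= ev[i]
    pulses[j] <- pulses[j] - depths[i] * exp(-(t[j] - ev[i]) / params$event_recovery_tau)
  }

  latent <- params$baseline_open_mean + ou + handling + treat + crab + prox + pulses
  frac <- pmin(pmax(latent, 0), 1)

  mussel_size <- if (is.null(metadata$mussel_size)) 4 else metadata$mussel_size
  max_gape_mm <- 2.2 * mussel_size
  mm <- frac * max_gape_mm
  md <- metadata
  md$treatment <- treatment; md$crab_condition <- condition
  if (is.null(md$mussel_id)) md$mussel_id <- "m1"
  if (is.null(md$trial_id)) md$trial_id <- "t1"

  structure(
    list(gape_raw = new_gape_trace(t, mm, unit = "mm",
                                   mussel_id = md$mussel_id),
         field_strength_au = synthetic_sensor_field(mm),
         crab_track = crab_track,
         metadata = md,
         truth = list(event_times_s = ev, max_gape_mm = max_gape_mm,
                      latent_step_at_switch = if (treatment == "boat")
                        params$sustained_boat_effect + params$sound_onset_drop else 0,
                      params = params)),
    class = "simulated_trial"
  )
}

poisson_times <- function(rate_per_s, start_s, end_s) {
  len <- end_s - start_s
  if (rate_per_s <= 0 || len <= 0) return(numeric(0))
  k <- stats::rpois(1, rate_per_s * len)
  sort(stats::runif(k, start_s, end_s))
}

#' Synthetic electromagnetic sensor response
#'
#' Monotone decreasing map from coil distance (mm) to field strength
#' (arbitrary units), used to emit raw logger readings for simulated animals;
#' [synthetic_sensor_calibration()] returns the matching knot table so the
#' calibration step can invert it.
#'
#' @param distance_mm Coil distances in mm.
#' @return Field strength in arbitrary units.
#' @export
synthetic_sensor_field <- function(distance_mm) 400 / (distance_mm + 4)

#' @rdname synthetic_sensor_field
#' @param max_mm Upper end of the calibrated distance range.
#' @param step_mm Knot spacing in mm.
#' @export
synthetic_sensor_calibration <- function(max_mm = 15, step_mm = 0.25) {
  d <- seq(0, max_mm, by = step_mm)
  calibration_model(synthetic_sensor_field(d), d)
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf("Simulated mussel %s (trial %s): %s / %s, %d samples, %d injected closures\n",
              x$metadata$mussel_id, x$metadata$trial_id, x$metadata$treatment,
              x$metadata$crab_condition, length(x$gape_raw$time_s),
              length(x$truth$event_times_s)))
  invisible(x)
}
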