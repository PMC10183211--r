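#' Simulation parameters for synthetic exposure trials
#'
#' Bundles every knob of the synthetic-trial generator. The latent
#' fraction-open path of a simulated mussel is
#' \deqn{f(t) = clip_{[0,1]}( baseline + OU(t) + handling(t) + treatment(t)
#'              + crab(t) + proximity(t) + pulses(t) )}
#' where \code{OU} is a mean-zero Ornstein--Uhlenbeck slow fluctuation,
#' \code{handling} is an exponential re-opening ramp after attachment of the
#' sensors, \code{treatment} is a sustained offset plus a decaying transient
#' onset drop applied from the sound switch in boat trials, \code{crab} is a
#' sustained offset applied from crab introduction in the crab-in-tank
#' condition, \code{proximity} is a level shift active while the simulated
#' crab is close to or touching the mussel, and \code{pulses} are injected
#' rapid-closure events (instantaneous drop, exponential re-opening) arriving
#' as a Poisson process with a phase-dependent rate.
#'
#' Effect offsets (\code{sound_onset_drop}, \code{sustained_boat_effect},
#' \code{crab_in_tank_effect}, \code{proximity_effect_slope}) are signed
#' fractions in \eqn{[-1, 1]}; negative values close the valves.
#'
#' @param baseline_open_mean Mean fraction open without any stimulus, in [0,1].
#' @param ou_theta Mean-reversion rate of the OU fluctuation (1/s).
#' @param ou_sigma Stationary standard deviation of the OU fluctuation
#'   (fraction-open units).
#' @param handling_reopen_tau Time constant (s) of the post-handling
#'   re-opening ramp; the trace starts fully closed and relaxes to baseline.
#'   0 disables the ramp.
#' @param sound_onset_drop Transient extra drop in fraction open at the sound
#'   switch, boat trials only (signed; default a small closure).
#' @param onset_recovery_tau Decay time constant (s) of the transient onset
#'   drop.
#' @param sustained_boat_effect Sustained offset applied for the whole
#'   treatment phase in boat trials (signed).
#' @param crab_in_tank_effect Sustained offset applied from crab introduction
#'   in the crab-in-tank condition (signed).
#' @param proximity_effect_slope Offset applied while the crab is close to or
#'   touching the mussel (signed; fraction open per unit of time-fraction
#'   spent close/touching when averaged over a window).
#' @param event_rate_baseline Rapid-closure rate outside the boat treatment,
#'   events per 10 min.
#' @param event_rate_boat Rapid-closure rate during the treatment phase of
#'   boat trials, events per 10 min.
#' @param event_depth_range Length-2 vector; closure depths are drawn
#'   uniformly from this range (fraction-open units).
#' @param event_recovery_tau Re-opening time constant (s) after a rapid
#'   closure.
#' @param min_event_gap_s Minimum gap enforced between injected closures (s).
#'   0 keeps the pure Poisson process; a positive gap thins later arrivals so
#'   every injected closure is temporally resolvable.
#' @param crab_transition_matrix 3x3 row-stochastic matrix of transition
#'   probabilities between the crab states \code{away}, \code{close},
#'   \code{touching} (rows = from, columns = to).
#' @param crab_dwell_mean_s Mean exponential dwell time per state (s);
#'   a scalar is recycled to all three states.
#' @param timestamp_jitter Logical; add uniform jitter of +/- 5% of the
#'   sampling interval to sample times (the logger's slight rate wobble).
#'   Default off.
#' @param seed Optional integer seed stored with the parameters; generator
#'   functions also accept an explicit seed argument.
#' @return An object of class \code{sim_params} (a validated list).
#' @examples
#' p <- sim_params()
#' p$sustained_boat_effect
#' @export
sim_params <- function(baseline_open_mean = 0.75,
                       ou_theta = 0.005,
                       ou_sigma = 0.08,
                       handling_reopen_tau = 300,
                       sound_onset_drop = -0.03,
                       onset_recovery_tau = 300,
                       sustained_boat_effect = -0.08,
                       crab_in_tank_effect = -0.05,
                       proximity_effect_slope = -0.3,
                       event_rate_baseline = 0.5,
                       event_rate_boat = 1.5,
                       event_depth_range = c(0.2, 0.5),
                       event_recovery_tau = 60,
                       min_event_gap_s = 0,
                       crab_transition_matrix = default_crab_transitions(),
                       crab_dwell_mean_s = c(60, 50, 10),
                       timestamp_jitter = FALSE,
                       seed = NULL) {
  p <- list(baseline_open_mean = baseline_open_mean,
            ou_theta = ou_theta, ou_sigma = ou_sigma,
            handling_reopen_tau = handling_reopen_tau,
            sound_onset_drop = sound_onset_drop,
            onset_recovery_tau = onset_recovery_tau,
            sustained_boat_effect = sustained_boat_effect,
            crab_in_tank_effect = crab_in_tank_effect,
            proximity_effect_slope = proximity_effect_slope,
            event_rate_baseline = event_rate_baseline,
            event_rate_boat = event_rate_boat,
            event_depth_range = event_depth_range,
            event_recovery_tau = event_recovery_tau,
            min_event_gap_s = min_event_gap_s,
            crab_transition_matrix = crab_transition_matrix,
            crab_dwell_mean_s = rep_len(crab_dwell_mean_s, 3),
            timestamp_jitter = isTRUE(timestamp_jitter),
            seed = seed)
  validate_sim_params(p)
  dimnames(p$crab_transition_matrix) <- list(crab_states(), crab_states())
  structure(p, class = "sim_params")
}

#' Default crab state-transition matrix
#'
#' Transition probabilities of the embedded chain over
#' \code{away}, \code{close}, \code{touching}. With the default dwell means
#' the long-run occupancy is roughly half away, slightly less close, and a
#' small touching fraction, matching the time budgets typically scored for a
#' free crab sharing a tank with a mussel.
#'
#' @return 3x3 row-stochastic matrix with dimnames over the state alphabet.
#' @export
default_crab_transitions <- function() {
  m <- matrix(c(0.00, 1.00, 0.00,
                0.85, 0.00, 0.15,
                0.00, 1.00, 0.00),
              nrow = 3, byrow = TRUE)
  dimnames(m) <- list(crab_states(), crab_states())
  m
}

#' Crab behavioural state alphabet
#' @return Character vector \code{c("away", "close", "touching")}.
#' @export
crab_states <- function() c("away", "close", "touching")

validate_sim_params <- function(p) {
  in01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  signed1 <- function(x) is.finite(x) && abs(x) <= 1
  if (!in01(p$baseline_open_mean))
    stop("baseline_open_mean must be a fraction in [0, 1]")
  if (!is.finite(p$ou_theta) || p$ou_theta < 0) stop("ou_theta must be >= 0")
  if (!in01(p$ou_sigma)) stop("ou_sigma must be in [0, 1]")
  for (nm in c("sound_onset_drop", "sustained_boat_effect",
               "crab_in_tank_effect", "proximity_effect_slope"))
    if (!signed1(p[[nm]])) stop(nm, " must be a signed fraction in [-1, 1]")
  if (!is.finite(p$handling_reopen_tau) || p$handling_reopen_tau < 0)
    stop("handling_reopen_tau must be >= 0 (0 disables the handling ramp)")
  for (nm in c("onset_recovery_tau", "event_recovery_tau"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) stop(nm, " must be positive")
  if (p$event_rate_baseline < 0 || p$event_rate_boat < 0)
    stop("event rates must be >= 0")
  if (length(p$event_depth_range) != 2 || !in01(p$event_depth_range) ||
      p$event_depth_range[1] > p$event_depth_range[2])
    stop("event_depth_range must be an increasing pair of fractions in [0, 1]")
  if (p$min_event_gap_s < 0) stop("min_event_gap_s must be >= 0")
  check_transition_matrix(p$crab_transition_matrix)
  if (any(!is.finite(p$crab_dwell_mean_s)) || any(p$crab_dwell_mean_s <= 0))
    stop("crab_dwell_mean_s must be positive")
  invisible(p)
}

check_transition_matrix <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(3L, 3L)) || any(!is.finite(m)))
    stop("crab_transition_matrix must be a finite 3x3 matrix")
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8))
    stop("crab_transition_matrix rows must be nonnegative and sum to 1")
  invisible(m)
}

#' Read / write simulation parameters as YAML
#'
#' The YAML mirrors the fields of [sim_params()]; the transition matrix is
#' stored as a list of three rows.
#'
#' @param params A [sim_params()] object.
#' @param path File path.
#' @return `write_sim_params()` returns `path` invisibly; `read_sim_params()`
#'   returns a validated [sim_params()] object.
#' @export
write_sim_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  x <- unclass(params)
  x$crab_transition_matrix <- lapply(seq_len(3),
                                     function(i) as.numeric(x$crab_transition_matrix[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_params
#' @export
read_sim_params <- function(path) {
  x <- yaml::read_yaml(path)
  x$crab_transition_matrix <- do.call(rbind, lapply(x$crab_transition_matrix, as.numeric))
  dimnames(x$crab_transition_matrix) <- list(crab_states(), crab_states())
  do.call(sim_params, x)
}
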