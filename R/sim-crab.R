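#' Simulate a crab state track
#'
#' Continuous-time semi-Markov simulation of the stimulus crab over the
#' states \code{away}, \code{close}, \code{touching}: exponential dwell times
#' with per-state means and an embedded transition matrix. The track starts
#' at crab introduction and covers the remainder of the trial.
#'
#' @param params A [sim_params()]; uses \code{crab_transition_matrix} and
#'   \code{crab_dwell_mean_s}.
#' @param protocol A [trial_protocol()].
#' @param start_state State at introduction (default \code{"away"}: the crab
#'   is released under its box).
#' @param seed Optional integer seed for reproducibility.
#' @return A [crab_track()] over \code{[crab_intro_s, total_duration_s)}.
#' @examples
#' tr <- simulate_crab_track(sim_params(), trial_protocol(), seed = 1)
#' time_budget(tr)
#' @export
simulate_crab_track <- function(params, protocol, start_state = "away",
                                seed = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(protocol, "trial_protocol"))
  check_transition_matrix(params$crab_transition_matrix)
  start_state <- match.arg(start_state, crab_states())
  if (!is.null(seed)) set.seed(seed)
  P <- params$crab_transition_matrix
  dwell <- rep_len(params$crab_dwell_mean_s, 3)
  names(dwell) <- crab_states()
  t0 <- protocol$crab_intro_s
  t_end <- protocol$total_duration_s
  cap <- 256L
  times <- numeric(cap); states <- character(cap)
  times[1] <- t0; states[1] <- start_state
  k <- 1L
  t <- t0
  s <- start_state
  repeat {
    t <- t + stats::rexp(1, rate = 1 / dwell[[s]])
    if (t >= t_end) break
    # absorbing state: no exit possible, dwell forever
    if (P[s, s] >= 1 - 1e-12) break
    nxt <- sample(crab_states(), 1, prob = P[s, ])
    if (nxt != s) {  # self-transitions leave the occupied state unchanged
      if (k == cap) {
        cap <- cap * 2L
        length(times) <- cap; length(states) <- cap
      }
      k <- k + 1L
      times[k] <- t; states[k] <- nxt
    }
    s <- nxt
  }
  crab_track(times[seq_len(k)], states[seq_len(k)], window = c(t0, t_end))
}

#' Long-run occupancy of the crab state process
#'
#' Stationary time-budget of the semi-Markov process: the stationary
#' distribution of the embedded chain weighted by mean dwell times. Used as
#' an analytic cross-check for the simulator.
#'
#' @param transition_matrix 3x3 row-stochastic embedded transition matrix.
#' @param dwell_mean_s Mean dwell times per state (recycled to length 3).
#' @return Named numeric vector of occupancy fractions summing to 1.
#' @export
crab_stationary_budget <- function(transition_matrix, dwell_mean_s = 1) {
  check_transition_matrix(transition_matrix)
  e <- eigen(t(transition_matrix))
  i <- which.min(abs(e$values - 1))
  pi_embedded <- abs(Re(e$vectors[, i]))
  pi_embedded <- pi_embedded / sum(pi_embedded)
  w <- pi_embedded * rep_len(dwell_mean_s, 3)
  out <- w / sum(w)
  names(out) <- crab_states()
  out
}
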