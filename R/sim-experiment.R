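#' Simulate a full counterbalanced experiment
#'
#' Generates \code{n_trials} trials of three mussels each. Sound treatments
#' alternate ambient/boat across trials; within every trial all three crab
#' conditions (no crab, crab in box, crab in tank) are tested simultaneously,
#' with the condition-to-position assignment rotated across trials. A crab
#' state track is simulated for the crab-in-tank mussel and drives its
#' proximity term. Mussel lengths are drawn uniformly from 3.1--5.4 cm and
#' crab carapace widths from 1.5--4.4 cm; the trial's stimulus crab size is
#' shared by all three records of that trial.
#'
#' Per-trial random streams are derived deterministically from the master
#' seed by a counter, so any subset of trials is reproducible on its own.
#'
#' @param n_trials Number of trials (>= 1). 59 trials reproduce the study
#'   scale of 177 mussel records.
#' @param params A [sim_params()].
#' @param protocol A [trial_protocol()].
#' @param master_seed Integer master seed.
#' @return List of \code{3 * n_trials} [simulate_gape_trace()] results, in
#'   trial order, with mussel ids \code{"t<trial>_m<pos>"}.
#' @examples
#' ex <- simulate_experiment(2, sim_params(), master_seed = 1)
#' length(ex)  # 6 mussel records
#' @export
simulate_experiment <- function(n_trials, params = sim_params(),
                                protocol = trial_protocol(), master_seed = 1) {
  stopifnot(n_trials >= 1)
  conditions <- c("no_crab", "crab_in_box", "crab_in_tank")
  out <- vector("list", 3 * n_trials)
  k <- 0
  for (trial in seq_len(n_trials)) {
    set.seed(trial_seed(master_seed, trial))
    treatment <- if (trial %% 2 == 1) "ambient" else "boat"
    rot <- (trial - 1) %% 3
    cond_order <- conditions[((seq_len(3) - 1 + rot) %% 3) + 1]
    crab_size <- round(stats::runif(1, 1.5, 4.4), 1)
    trial_id <- sprintf("t%03d", trial)
    for (pos in seq_len(3)) {
      condition <- cond_order[pos]
      mussel_size <- round(stats::runif(1, 3.1, 5.4), 1)
      track <- if (condition == "crab_in_tank")
        simulate_crab_track(params, protocol) else NULL
      md <- list(treatment = treatment, crab_condition = condition,
                 mussel_size = mussel_size, crab_size = crab_size,
                 trial_id = trial_id,
                 mussel_id = sprintf("%s_m%d", trial_id, pos))
      k <- k + 1
      out[[k]] <- simulate_gape_trace(params, protocol, md, crab_track = track)
    }
  }
  out
}

trial_seed <- function(master_seed, trial) {
  (as.integer(master_seed) + 97003L * as.integer(trial)) %% 2147483647L
}

#' Metadata table of a simulated experiment
#'
#' @param trials Output of [simulate_experiment()].
#' @return Data frame with one row per mussel record: \code{trial_id},
#'   \code{mussel_id}, \code{treatment}, \code{crab_condition},
#'   \code{mussel_size}, \code{crab_size}, \code{n_injected_events}.
#' @export
experiment_metadata <- function(trials) {
  do.call(rbind, lapply(trials, function(tr) {
    m <- tr$metadata
    data.frame(trial_id = m$trial_id, mussel_id = m$mussel_id,
               treatment = m$treatment, crab_condition = m$crab_condition,
               mussel_size = m$mussel_size, crab_size = m$crab_size,
               n_injected_events = length(tr$truth$event_times_s),
               stringsAsFactors = FALSE)
  }))
}

#' Write a simulated experiment to disk
#'
#' Emits the standard file set: gape logs (\code{gape.csv}), crab transition
#' logs (\code{crab.csv}), trial metadata (\code{metadata.csv}) and injected
#' ground truth (\code{truth.json}).
#'
#' @param trials Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_experiment <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gape_path <- file.path(dir, "gape.csv")
  write_gape_csv(trials, gape_path)
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(experiment_metadata(trials), meta_path,
                   row.names = FALSE, quote = FALSE)
  tracks <- list()
  for (tr in trials)
    if (!is.null(tr$crab_track)) tracks[[tr$metadata$trial_id]] <- tr$crab_track
  crab_path <- file.path(dir, "crab.csv")
  write_crab_csv(tracks, crab_path)
  truth <- lapply(trials, function(tr) tr$truth$event_times_s)
  names(truth) <- vapply(trials, function(tr) tr$metadata$mussel_id, character(1))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, digits = NA)
  invisible(c(gape_path, crab_path, meta_path, truth_path))
}
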