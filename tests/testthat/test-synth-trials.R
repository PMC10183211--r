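test_that("protocol validates its timeline and exposes half-open windows", {
  p <- trial_protocol()
  expect_equal(p$phases$start_s, c(0, 1500, 3000))
  expect_equal(p$phases$end_s, c(1500, 3000, 4500))
  expect_lt(p$crab_intro_s, p$sound_switch_s)
  w <- analysis_windows(p)
  expect_equal(w$long_baseline, c(2400, 2640))
  expect_equal(w$long_treatment, c(3000, 4500))
  expect_equal(w$event_baseline, c(1230, 2640))
  expect_equal(w$event_treatment, c(3030, 4500))
  expect_error(trial_protocol(crab_intro_s = 3200), "crab_intro_s")
  tt <- protocol_times(p)
  expect_true(all(diff(tt) > 0))
  expect_lt(max(tt), p$total_duration_s)
  # ~47.3 samples per minute at the default interval
  expect_equal(60 / p$sample_interval_s, 47.24, tolerance = 0.01)
})

test_that("crab track simulation: absorbing case, determinism, occupancy", {
  pr <- trial_protocol()
  p_abs <- sim_params(crab_transition_matrix = diag(3))
  tr <- simulate_crab_track(p_abs, pr, start_state = "away", seed = 5)
  b <- time_budget(tr)
  expect_equal(c(b$fraction_away, b$fraction_close, b$fraction_touching),
               c(1, 0, 0))

  p <- sim_params()
  t1 <- simulate_crab_track(p, pr, seed = 42)
  t2 <- simulate_crab_track(p, pr, seed = 42)
  expect_identical(t1$transitions, t2$transitions)

  bad <- matrix(1, 3, 3)
  expect_error(sim_params(crab_transition_matrix = bad), "sum to 1")
})

test_that("uniform-chain occupancy approaches the stationary distribution", {
  # long-run budget of the uniform chain: computed two independent ways
  unif <- matrix(1 / 3, 3, 3, dimnames = list(crab_states(), crab_states()))
  expect_equal(unname(crab_stationary_budget(unif, 1)), rep(1 / 3, 3),
               tolerance = 1e-12)
  p <- sim_params(crab_transition_matrix = unif, crab_dwell_mean_s = 20)
  # one long window: total duration chosen to give ~1e5 dwell steps
  pr <- trial_protocol(total_duration_s = 2e6, phase_boundaries_s = c(10, 20),
                       crab_intro_s = 30, sound_switch_s = 40)
  b <- time_budget(simulate_crab_track(p, pr, seed = 7))
  expect_equal(b$fraction_away, 1 / 3, tolerance = 0.02)
  expect_equal(b$fraction_close, 1 / 3, tolerance = 0.02)
  expect_equal(b$fraction_touching, 1 / 3, tolerance = 0.02)
})

test_that("gape simulation degenerate limit is a constant trace at baseline", {
  p <- sim_params(ou_sigma = 0, sound_onset_drop = 0,
                  sustained_boat_effect = 0, crab_in_tank_effect = 0,
                  proximity_effect_slope = 0, event_rate_baseline = 0,
                  event_rate_boat = 0, handling_reopen_tau = 0)
  tr <- simulate_gape_trace(p, trial_protocol(),
                            list(treatment = "boat", crab_condition = "no_crab",
                                 mussel_size = 4, crab_size = 3), seed = 1)
  frac <- tr$gape_raw$value / tr$truth$max_gape_mm
  expect_equal(frac, rep(p$baseline_open_mean, length(frac)), tolerance = 1e-12)
  expect_length(tr$truth$event_times_s, 0)
})

test_that("latent path steps by the onset drop at the sound switch", {
  p <- sim_params(ou_sigma = 0, sound_onset_drop = -0.2,
                  onset_recovery_tau = 1e7,
                  sustained_boat_effect = 0, crab_in_tank_effect = 0,
                  proximity_effect_slope = 0, event_rate_baseline = 0,
                  event_rate_boat = 0, handling_reopen_tau = 0)
  pr <- trial_protocol()
  tr <- simulate_gape_trace(p, pr, list(treatment = "boat",
                                        crab_condition = "no_crab",
                                        mussel_size = 4, crab_size = 3), seed = 1)
  frac <- tr$gape_raw$value / tr$truth$max_gape_mm
  t <- tr$gape_raw$time_s
  pre <- frac[max(which(t < pr$sound_switch_s))]
  post <- frac[min(which(t >= pr$sound_switch_s))]
  expect_equal(post - pre, -0.2, tolerance = 1e-6)
})

test_that("injected pulse count is Poisson with the boat-phase rate", {
  r <- 2  # events per 10 min in the boat phase only
  p <- sim_params(ou_sigma = 0, event_rate_baseline = 0, event_rate_boat = r,
                  handling_reopen_tau = 0, sound_onset_drop = 0,
                  sustained_boat_effect = 0)
  pr <- trial_protocol()
  md <- list(treatment = "boat", crab_condition = "no_crab",
             mussel_size = 4, crab_size = 3)
  counts <- vapply(seq_len(500), function(s)
    length(simulate_gape_trace(p, pr, md, seed = s)$truth$event_times_s),
    numeric(1))
  expected <- r * 2.5              # 25 min of boat phase
  se <- sqrt(expected / 500)       # Poisson variance = mean
  expect_lt(abs(mean(counts) - expected), 3 * se)
  expect_true(all(vapply(seq_len(20), function(s) {
    ev <- simulate_gape_trace(p, pr, md, seed = s)$truth$event_times_s
    !length(ev) || all(ev >= pr$sound_switch_s & ev < pr$total_duration_s)
  }, logical(1))))
})

test_that("latent fraction paths are clipped to [0,1] and mm traces nonnegative", {
  p <- sim_params(ou_sigma = 0.4, event_rate_boat = 6)  # deliberately wild
  pr <- trial_protocol()
  for (s in 1:5) {
    tr <- simulate_gape_trace(p, pr, list(treatment = "boat",
                                          crab_condition = "no_crab",
                                          mussel_size = 4, crab_size = 3),
                              seed = s)
    frac <- tr$gape_raw$value / tr$truth$max_gape_mm
    expect_true(all(frac >= 0 & frac <= 1))
    expect_true(all(tr$gape_raw$value >= 0))
  }
})

test_that("experiment generation is balanced and reproducible", {
  ex <- simulate_experiment(2, master_seed = 3)
  expect_length(ex, 6)
  md <- experiment_metadata(ex)
  expect_equal(unname(table(md$crab_condition)[c("no_crab", "crab_in_box",
                                                 "crab_in_tank")]),
               rep(2L, 3), ignore_attr = TRUE)
  expect_setequal(unique(md$treatment), c("ambient", "boat"))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(simulate_experiment(2, master_seed = 9), d1)
  write_experiment(simulate_experiment(2, master_seed = 9), d2)
  for (f in c("gape.csv", "crab.csv", "metadata.csv", "truth.json"))
    expect_identical(readBin(file.path(d1, f), raw(), 1e7),
                     readBin(file.path(d2, f), raw(), 1e7))
})

test_that("null simulations center the long-term response on zero", {
  p <- sim_params(sound_onset_drop = 0, sustained_boat_effect = 0,
                  crab_in_tank_effect = 0, proximity_effect_slope = 0,
                  event_rate_boat = 0.5)
  pr <- trial_protocol()
  md <- list(treatment = "boat", crab_condition = "no_crab",
             mussel_size = 4, crab_size = 3)
  deltas <- vapply(seq_len(200), function(s) {
    tr <- simulate_gape_trace(p, pr, md, seed = 1000 + s)
    long_term_response(normalize_fraction_open(tr$gape_raw), pr)
  }, numeric(1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se)
})

test_that("simulation parameters survive a YAML round trip", {
  p <- sim_params(sustained_boat_effect = -0.123, crab_dwell_mean_s = c(30, 40, 5))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_params(p, f)
  q <- read_sim_params(f)
  expect_equal(unclass(q)[names(unclass(p))], unclass(p), tolerance = 1e-12)
})
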