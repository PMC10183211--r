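test_that("moving average: constant, ramp, and impulse responses", {
  const <- gape_trace(1:30, rep(0.5, 30), "fraction")
  ma <- moving_average(const, 15)
  expect_length(ma$time_s, 30 - 14)
  expect_equal(ma$value, rep(0.5, 16))

  ramp <- gape_trace(1:41, seq(0, 1, length.out = 41), "fraction")
  mr <- moving_average(ramp, 15)
  expect_equal(mr$value, ramp$value[8:34], tolerance = 1e-12)  # centered mean of a line
  expect_equal(mr$time_s, ramp$time_s[8:34])

  imp <- gape_trace(1:61, c(rep(0, 30), 1, rep(0, 30)), "fraction")
  mi <- moving_average(imp, 15)
  # brute-force convolution oracle
  expect_equal(mi$value, vapply(8:54, function(i) mean(imp$value[(i-7):(i+7)]),
                                numeric(1)), tolerance = 1e-12)
  expect_equal(sum(mi$value > 0), 15)
  expect_equal(unique(round(mi$value[mi$value > 0], 12)), round(1/15, 12))

  expect_error(moving_average(const, 14), "odd")
  expect_error(moving_average(gape_trace(1:5, 1:5/10, "fraction"), 15),
               "insufficient")
})

test_that("delta series telescopes and is stamped at the later point", {
  ma <- gape_trace(c(1, 2, 3), c(0.5, 0.5, 0.5), "fraction")
  expect_equal(delta_ma(ma)$dma, c(0, 0))
  two <- gape_trace(c(1, 2), c(1.0, 0.4), "fraction")
  d2 <- delta_ma(two)
  expect_equal(d2$dma, -0.6)
  expect_equal(d2$time_s, 2)
  set.seed(3)
  x <- gape_trace(1:50, runif(50), "fraction")
  d <- delta_ma(x)
  expect_equal(sum(d$dma), x$value[50] - x$value[1], tolerance = 1e-12)
})

test_that("robust threshold: worked example, degenerate flag, normal-theory value", {
  thr <- robust_threshold(c(-2, -1, 0, 1, 2))
  expect_equal(as.numeric(thr), -15)
  expect_false(attr(thr, "degenerate"))

  flat <- robust_threshold(rep(0.3, 10))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))

  # on N(0, sigma) differences the central-subset SD approaches the SD of a
  # normal truncated to its interquartile range: sqrt(1 - 4 q phi(q)), with
  # q = qnorm(0.75) -- about 0.37769
  sigma <- 0.02
  q <- qnorm(0.75)
  trunc_sd <- sqrt(1 - 4 * q * dnorm(q))
  set.seed(11)
  mc <- rnorm(2e6, 0, sigma)
  mc_sub <- mc[mc >= quantile(mc, 0.25) & mc <= quantile(mc, 0.75)]
  expect_equal(sd(mc_sub), trunc_sd * sigma, tolerance = 0.005)  # MC oracle
  thr_n <- robust_threshold(rnorm(2e5, 0, sigma))
  expect_equal(as.numeric(thr_n), -15 * trunc_sd * sigma, tolerance = 0.01)
})

test_that("detector finds single and merged closures as maximal runs", {
  n <- 400
  t <- seq(0, by = 1.27, length.out = n)
  base <- 0.6 + 0.02 * sin(seq(0, 8 * pi, length.out = n))  # finite spread
  drop_at <- function(x, i, depth) {
    x[i:n] <- x[i:n] - depth * exp(-(t[i:n] - t[i]) / 40)
    x
  }
  one <- gape_trace(t, drop_at(base, 200, 0.5), "fraction")
  ev1 <- detect_events(one)
  expect_length(ev1$event_times_s, 1)

  two_far <- gape_trace(t, drop_at(drop_at(base, 120, 0.5), 300, 0.5), "fraction")
  expect_length(detect_events(two_far)$event_times_s, 2)

  two_near <- gape_trace(t, drop_at(drop_at(base, 200, 0.5), 201, 0.5), "fraction")
  expect_length(detect_events(two_near)$event_times_s, 1)  # merged run

  const <- gape_trace(t, rep(0.6, n), "fraction")
  expect_warning(ev0 <- detect_events(const), "degenerate")
  expect_length(ev0$event_times_s, 0)
})

test_that("detector matches the brute-force oracle on random traces", {
  set.seed(21)
  for (i in 1:40) {
    tr <- random_test_trace(n = 600)
    got <- detect_events(tr)
    want <- oracle_detect(tr$time_s, tr$value)
    expect_equal(got$event_times_s, want$event_times, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
  }
})

test_that("event count is monotone in threshold severity and scale-invariant", {
  set.seed(33)
  for (i in 1:10) {
    tr <- random_test_trace(n = 800, n_drops = 3)
    counts <- vapply(c(-5, -10, -15, -20),
                     function(m) length(detect_events(tr, multiplier = m)$event_times_s),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
    scaled <- gape_trace(tr$time_s, 0.37 * tr$value, "fraction")
    expect_equal(detect_events(scaled)$event_times_s,
                 detect_events(tr)$event_times_s)
  }
})

test_that("event-rate change uses per-10-min rates over the margin windows", {
  pr <- trial_protocol()
  ev <- structure(list(event_times_s = c(seq(1300, 2600, length.out = 4),
                                         seq(3100, 4400, length.out = 7)),
                       event_dma = rep(-1, 11), threshold = -0.5,
                       window = 15, multiplier = -15, degenerate = FALSE,
                       trace_id = "x"), class = "closing_events")
  rc <- event_rate_change(ev, pr)
  expect_equal(rc$baseline_count, 4)
  expect_equal(rc$treatment_count, 7)
  expect_equal(rc$baseline_rate, 4 / 2.35, tolerance = 1e-12)   # 23.5 min
  expect_equal(rc$treatment_rate, 7 / 2.45, tolerance = 1e-12)  # 24.5 min
  expect_equal(rc$delta_rate, 7 / 2.45 - 4 / 2.35, tolerance = 1e-12)

  none <- ev; none$event_times_s <- numeric(0)
  rc0 <- event_rate_change(none, pr)
  expect_equal(c(rc0$baseline_rate, rc0$treatment_rate, rc0$delta_rate),
               c(0, 0, 0))
})

test_that("noise-free detection recovers the injected treatment-phase rate", {
  pr <- trial_protocol()
  p <- noise_free_params(event_rate_baseline = 0, event_rate_boat = 2)
  md <- list(treatment = "boat", crab_condition = "no_crab",
             mussel_size = 4, crab_size = 3)
  # a detected run starts at the first changed moving-average difference,
  # up to about half a window before the injected drop
  lead <- 15 * pr$sample_interval_s
  for (s in 1:10) {
    tr <- simulate_gape_trace(p, pr, md, seed = 100 + s)
    frac <- normalize_fraction_open(tr$gape_raw)
    ev <- suppressWarnings(detect_events(frac))
    truth <- tr$truth$event_times_s
    rc <- event_rate_change(ev, pr)
    w <- analysis_windows(pr)
    expect_identical(length(ev$event_times_s), length(truth))
    expect_equal(rc$baseline_count, 0)
    expect_gte(rc$treatment_count,
               sum(truth >= w$event_treatment[1] + lead &
                     truth < w$event_treatment[2]))
    expect_lte(rc$treatment_count,
               sum(truth >= w$event_treatment[1] - lead &
                     truth < w$event_treatment[2]))
  }
})
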