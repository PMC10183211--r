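# Independent brute-force oracles, written as explicit loops so they share no
# code path with the package implementation.

oracle_quantile <- function(x, p) {
  # type-7 linear-interpolation quantile, derived from first principles
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_detect <- function(time_s, value, window = 15, multiplier = -15) {
  n <- length(value)
  half <- (window - 1) / 2
  ma <- numeric(0); ma_t <- numeric(0)
  for (i in (half + 1):(n - half)) {
    acc <- 0
    for (j in (i - half):(i + half)) acc <- acc + value[j]
    ma <- c(ma, acc / window)
    ma_t <- c(ma_t, time_s[i])
  }
  dma <- numeric(0); dma_t <- numeric(0)
  for (i in 2:length(ma)) {
    dma <- c(dma, ma[i] - ma[i - 1])
    dma_t <- c(dma_t, ma_t[i])
  }
  q1 <- oracle_quantile(dma, 0.25)
  q3 <- oracle_quantile(dma, 0.75)
  sub <- dma[dma >= q1 & dma <= q3]
  s <- oracle_sd(sub)
  if (!is.finite(s) || s <= 0)
    return(list(event_times = numeric(0), threshold = 0))
  thr <- multiplier * s
  ev <- numeric(0)
  in_run <- FALSE
  for (i in seq_along(dma)) {
    if (dma[i] < thr) {
      if (!in_run) ev <- c(ev, dma_t[i])
      in_run <- TRUE
    } else in_run <- FALSE
  }
  list(event_times = ev, threshold = thr)
}

# random fraction-open-like test trace: smooth wander plus sharp drops
random_test_trace <- function(n = 1100, n_drops = sample(0:4, 1), id = "r") {
  t <- seq(0, by = 1.27, length.out = n)
  x <- 0.6 + 0.15 * sin(seq(0, 6 * pi, length.out = n)) +
    cumsum(rnorm(n, 0, 0.004))
  if (n_drops > 0) {
    at <- sample(seq(20, n - 20), n_drops)
    for (i in at) {
      depth <- runif(1, 0.2, 0.6)
      tail <- i:n
      x[tail] <- x[tail] - depth * exp(-(t[tail] - t[i]) / 60)
    }
  }
  x <- (x - min(x)) / (max(x) - min(x))
  gape_trace(t, x, unit = "fraction", mussel_id = id)
}

# noise-free simulator configuration: only injected pulses move the trace
# (plus the handling ramp, which keeps the robust threshold finite)
noise_free_params <- function(...) {
  sim_params(ou_sigma = 0, sound_onset_drop = 0, sustained_boat_effect = 0,
             crab_in_tank_effect = 0, proximity_effect_slope = 0,
             min_event_gap_s = 30, ...)
}
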