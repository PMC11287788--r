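# Per-cell PSC summaries.

test_that("frequency is the exact event count over duration", {
  expect_equal(psc_frequency(seq(1, 240, length.out = 24), 240), 0.1)
  expect_equal(psc_frequency(numeric(0), 240), 0)  # meaningful zero
  expect_error(psc_frequency(c(1, 2), 0), "duration_s")
})

test_that("frequency estimates are unbiased for Poisson event trains", {
  set.seed(4)
  freqs <- vapply(1:500, function(i) {
    n <- rpois(1, 180)
    psc_frequency(sort(runif(n, 0, 180)), 180)
  }, numeric(1))
  se <- sd(freqs) / sqrt(500)
  expect_lt(abs(mean(freqs) - 1), 3 * se)
})

test_that("interevent intervals use the backward convention", {
  expect_equal(interevent_intervals(c(1.0, 1.5, 2.1)), c(0.5, 0.6))
  expect_equal(interevent_intervals(c(3.2)), numeric(0))  # first unknown
  expect_error(interevent_intervals(c(2, 1)), "ordered")
})

test_that("intervals match exhaustive successor differences", {
  set.seed(7)
  for (i in 1:20) {
    t_s <- sort(runif(sample(2:40, 1), 0, 100))
    brute <- vapply(2:length(t_s), function(j) t_s[j] - t_s[j - 1],
                    numeric(1))
    expect_equal(interevent_intervals(t_s), brute)
    expect_equal(length(interevent_intervals(t_s)), length(t_s) - 1)
  }
})

test_that("amplitude eligibility follows the 200 ms rules", {
  ev <- data.frame(peak_time_s = c(0.15, 0.40, 0.55),
                   amplitude_pa = c(10, 20, 30))
  # first too close to start (0.15 <= 0.2); third interval 0.15 < 0.2
  expect_equal(eligible_amplitudes(ev), 20)
  # a lone event >200 ms after the start is included
  expect_equal(
    eligible_amplitudes(data.frame(peak_time_s = 0.25, amplitude_pa = 12)),
    12
  )
  # first event qualifies, closely following events do not
  ev2 <- data.frame(peak_time_s = c(1.0, 1.1, 1.2, 1.3),
                    amplitude_pa = c(5, 6, 7, 8))
  expect_equal(eligible_amplitudes(ev2), 5)
  # the backward-interval comparison is inclusive at exactly 200 ms
  ev3 <- data.frame(peak_time_s = c(1.0, 1.2), amplitude_pa = c(5, 6))
  expect_equal(eligible_amplitudes(ev3), c(5, 6))
})

test_that("eligible amplitudes are a monotone subset of event amplitudes", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    ev <- data.frame(peak_time_s = sort(runif(n, 0, 10)),
                     amplitude_pa = runif(n, 5, 50))
    loose <- eligible_amplitudes(ev, config = metric_config(
      amplitude_min_backward_interval_s = 0.1
    ))
    strict <- eligible_amplitudes(ev, config = metric_config(
      amplitude_min_backward_interval_s = 0.3
    ))
    expect_true(all(strict %in% loose))
    expect_true(all(loose %in% ev$amplitude_pa))
  }
})

test_that("isolated-event averaging recovers the template", {
  fs <- 10000
  tau_r <- 0.001
  tau_d <- 0.015
  t_s <- (0:(6 * fs - 1)) / fs
  x <- rep(0, length(t_s))
  peaks <- c(1, 2.5, 4) + tau_r * log(1 + tau_d / tau_r)
  for (t0 in c(1, 2.5, 4)) {
    on <- pmax(t_s - t0, 0)
    x <- x + 30 * ((1 - exp(-on / tau_r)) * exp(-on / tau_d) *
                     (t_s >= t0)) /
      ((1 - exp(-log(16))) * exp(-tau_r * log(16) / tau_d))
  }
  ev <- data.frame(peak_time_s = peaks, baseline_pa = 0,
                   amplitude_pa = rep(30, 3))
  wf <- isolated_event_average(ev, psc_trace(x, fs))
  expect_equal(wf$n_events, 3)
  expect_equal(max(wf$waveform), 1)
  ref <- dense_template((seq_along(wf$waveform) - wf$peak_index) / fs +
                          tau_r * log(1 + tau_d / tau_r), tau_r, tau_d)
  expect_lt(sqrt(mean((wf$waveform - ref)^2)), 0.02)
})

test_that("events with a short gap on either side are excluded", {
  # the 150 ms gap disqualifies both events adjacent to it
  idx <- pscpipe:::isolated_event_indices(c(1.0, 2.0, 2.15), 10)
  expect_equal(idx, 1L)
  # first/last events use the gap to the recording boundaries
  idx2 <- pscpipe:::isolated_event_indices(c(0.1, 5), 5.1)
  expect_equal(idx2, integer(0))
})

test_that("noisy isolated-event averages converge to the template", {
  sim <- generate_psc_trace(trace_spec(
    duration_s = 120, event_rate_hz = 0.4, amplitude_mean_pa = 30,
    amplitude_cv = 0, noise_sd_pa = 2, seed = 31
  ))
  ev <- detect_events(sim$trace)
  wf <- isolated_event_average(ev, sim$trace)
  expect_gte(wf$n_events, 20)
  ref <- dense_template((seq_along(wf$waveform) - wf$peak_index) / 10000 +
                          0.001 * log(16), 0.001, 0.015)
  rms <- sqrt(mean((wf$waveform - ref)^2))
  expect_lt(rms, 0.05)
})

test_that("80-20 decay matches the exponential closed form", {
  t_ms <- seq(0, 400, by = 0.1)
  expect_equal(decay_time_80_20(exp(-t_ms / 10), 10000), 10 * log(4),
               tolerance = 1e-3)
  expect_equal(decay_time_80_20(exp(-t_ms / 5), 10000), 5 * log(4),
               tolerance = 1e-3)
  expect_error(decay_time_80_20(c(1, 0.9, 0.85), 10000), "20%")
})

test_that("biexponential decay matches a dense numeric oracle", {
  fs <- 10000
  t_s <- seq(0, 0.4, by = 1 / fs)
  w <- dense_template(t_s, 0.002, 0.02)
  got <- decay_time_80_20(w, fs)
  # dense evaluation at 1 MHz as the oracle
  t_hi <- seq(0, 0.4, by = 1e-6)
  w_hi <- dense_template(t_hi, 0.002, 0.02)
  pk <- which.max(w_hi)
  t80 <- t_hi[pk - 1 + which(w_hi[pk:length(w_hi)] < 0.8)[1]]
  t20 <- t_hi[pk - 1 + which(w_hi[pk:length(w_hi)] < 0.2)[1]]
  expect_equal(got, (t20 - t80) * 1000, tolerance = 0.01)
})

test_that("decay time scales linearly with time-axis dilation", {
  t_ms <- seq(0, 500, by = 0.05)
  base <- decay_time_80_20(exp(-t_ms / 8), 20000)
  dilated <- decay_time_80_20(exp(-t_ms / 16), 20000)
  expect_equal(dilated / base, 2, tolerance = 1e-3)
})

test_that("cumulative distributions match the rank construction", {
  got <- cumulative_distribution(c(2, 1, 2))
  expect_equal(got$value, c(1, 2))
  expect_equal(got$cumprob, c(1 / 3, 1))
  same <- cumulative_distribution(rep(7, 5))
  expect_equal(same, data.frame(value = 7, cumprob = 1))
  expect_error(cumulative_distribution(numeric(0)), "at least one")
  set.seed(8)
  for (i in 1:10) {
    v <- sample(round(rnorm(40), 1), 40, replace = TRUE)
    expect_equal(cumulative_distribution(v), ecdf_oracle(v))
  }
})

test_that("summarize_cell assembles every per-cell metric", {
  sim <- generate_psc_trace(trace_spec(duration_s = 60, event_rate_hz = 0.5,
                                       seed = 17))
  ev <- detect_events(sim$trace)
  sm <- summarize_cell(ev, sim$trace)
  expect_s3_class(sm, "cell_event_summary")
  expect_equal(sm$frequency_hz, nrow(ev) / 60)
  expect_equal(length(sm$intervals_s), nrow(ev) - 1)
  expect_true(all(sm$eligible_amplitudes_pa %in% ev$amplitude_pa))
  expect_gt(sm$decay_time_80_20_ms, 0)
  # zero-event cell: frequency 0, no interval statistics
  empty <- summarize_cell(ev[0, ], duration_s = 60)
  expect_equal(empty$frequency_hz, 0)
  expect_true(is.na(empty$mean_interval_s))
})
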