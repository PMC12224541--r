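test_that("protocol descriptors expand to the expected stimulus times", {
  p1 <- stim_protocol(frequency_hz = 1, n_bursts = 15, start_s = 0.5)
  expect_length(p1$times_s, 15)
  expect_equal(p1$times_s, seq(0.5, 14.5, by = 1))

  p10 <- stim_protocol(frequency_hz = 10, pulses_per_burst = 5,
                       burst_period_s = 2, n_bursts = 2)
  expect_length(p10$times_s, 10)
  gaps <- diff(p10$times_s)
  expect_equal(gaps[1:4], rep(0.1, 4))
  expect_equal(gaps[5], 1.6)

  p5 <- stim_protocol(frequency_hz = 5, pulses_per_burst = 5,
                      burst_period_s = 2, n_bursts = 1)
  expect_equal(unique(round(diff(p5$times_s), 10)), 0.2)

  expect_error(stim_protocol(frequency_hz = 2, pulses_per_burst = 5,
                             burst_period_s = 2, n_bursts = 2),
               class = "synca_protocol_error")
  expect_error(stim_protocol(times_s = c(1, 1)), class = "synca_protocol_error")

  td <- tidy(p10)
  expect_equal(td$position, rep(1:5, 2))
  expect_equal(td$burst, rep(1:2, each = 5))
})

test_that("partitioning assigns every stimulus exactly once", {
  p <- stim_protocol(frequency_hz = 1, n_bursts = 15, start_s = 0.5)
  ev <- tibble::tibble(peak_time_s = p$times_s + 0.03,
                       amplitude = rep(0.6, 15))
  asg <- partition_evoked(ev, p)
  expect_identical(nrow(asg), 15L)
  expect_false(any(asg$failure))
  expect_equal(attr(asg, "failure_rate"), 0)
  # each event used at most once
  expect_identical(anyDuplicated(asg$event_index[!asg$failure]), 0L)

  # dropping event 7 yields exactly one failure
  asg2 <- partition_evoked(ev[-7, ], p)
  expect_identical(sum(asg2$failure), 1L)
  expect_equal(attr(asg2, "failure_rate"), 1 / 15)
  expect_equal(asg2$amplitude[asg2$failure], 0)
  g <- glance(asg2)
  expect_identical(g$n_failures, 1L)
})

test_that("partitioning is causal and conserves events under random gaps", {
  set.seed(13)
  for (i in 1:10) {
    p <- stim_protocol(frequency_hz = 5, pulses_per_burst = 5,
                       burst_period_s = 2, n_bursts = 3, start_s = 0.4)
    keep <- runif(15) > 0.3
    ev <- tibble::tibble(peak_time_s = (p$times_s + runif(15, 0.01, 0.15))[keep],
                         amplitude = runif(15)[keep])
    asg <- partition_evoked(ev, p)
    expect_identical(nrow(asg), 15L)
    expect_identical(sort(unique(asg$stimulus)), 1:15)
    assigned <- asg$event_index[!asg$failure]
    expect_identical(anyDuplicated(assigned), 0L)
    expect_true(all(asg$event_peak_time_s[!asg$failure] >
                      asg$stimulus_time_s[!asg$failure]))
    expect_equal(attr(asg, "failure_rate"), mean(asg$failure))
  }
})

test_that("an over-long response window is clipped with a warning", {
  p <- stim_protocol(frequency_hz = 10, pulses_per_burst = 5,
                     burst_period_s = 2, n_bursts = 1)
  ev <- tibble::tibble(peak_time_s = p$times_s + 0.02, amplitude = rep(1, 5))
  expect_warning(asg <- partition_evoked(ev, p, response_window_s = 0.3),
                 "clipped")
  expect_equal(attr(asg, "response_window_s"), 0.1)
})

test_that("train summary reports facilitation relative to position 1", {
  asg <- tibble::tibble(position = rep(1:5, 3), amplitude = rep(2, 15),
                        failure = rep(FALSE, 15))
  s <- train_summary(asg)
  expect_equal(s$facilitation_index, rep(1, 5))
  # an all-failure position is NA, not zero
  asg$failure[asg$position == 3] <- TRUE
  s2 <- train_summary(asg)
  expect_true(is.na(s2$mean_amplitude[s2$position == 3]))
  expect_error(train_summary(asg[0, ]), class = "synca_parameter_error")
})

test_that("train peaks follow closed-form superposition of decay tails", {
  # 10 Hz, tau_decay 100 ms: position-5 raw peak exceeds position 1 by the
  # analytic sum of the preceding tails
  tr <- 0.005; td <- 0.1; A <- 1
  p <- stim_protocol(frequency_hz = 10, pulses_per_burst = 5,
                     burst_period_s = 2, n_bursts = 1, start_s = 0.5)
  dt <- 1 / 1000
  t <- seq(0, 2.5, by = dt)
  v <- rowSums(vapply(p$times_s, function(e) {
    A * oracle_kernel_unit(t - e, tr, td)
  }, numeric(length(t))))
  ta <- train_amplitudes(v, p, smooth = FALSE, time = t)
  pk_t <- oracle_kernel_peak_t(tr, td)
  peak5_t <- p$times_s[5] + pk_t
  predicted <- sum(A * oracle_kernel_unit(peak5_t - p$times_s, tr, td))
  expect_equal(ta$raw_peak[5], predicted, tolerance = 0.01)
  expect_gt(ta$raw_peak[5], ta$raw_peak[1])
  # segment-relative amplitudes stay comparable across the burst
  expect_true(all(abs(ta$amplitude / ta$amplitude[1] - 1) < 0.15))
})

test_that("train partition amplitudes agree with single-event segmentation", {
  # events riding on tails: segment-relative amplitude within 2% of the
  # isolated-event amplitude minus the superposed tail
  tr <- 0.0053; td <- 0.0666; A <- 0.4
  p <- stim_protocol(frequency_hz = 10, pulses_per_burst = 5,
                     burst_period_s = 2, n_bursts = 1, start_s = 0.5)
  dt <- 1 / 1000
  t <- seq(0, 2.5, by = dt)
  v <- rowSums(vapply(p$times_s, function(e) {
    A * oracle_kernel_unit(t - e, tr, td)
  }, numeric(length(t))))
  ta <- train_amplitudes(v, p, smooth = FALSE, time = t)
  for (k in 2:5) {
    iso <- A * max(oracle_kernel_unit(t - p$times_s[k], tr, td))
    tail_at_peak <- sum(A * oracle_kernel_unit(
      ta$peak_time_s[k] - p$times_s[seq_len(k - 1)], tr, td))
    tail_at_base <- sum(A * oracle_kernel_unit(
      p$times_s[k] - p$times_s[seq_len(k - 1)], tr, td))
    manual <- iso + tail_at_peak - tail_at_base
    expect_lt(abs(ta$amplitude[k] - manual) / manual, 0.02)
  }
})
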