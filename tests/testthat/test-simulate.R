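test_that("the sampled kernel is unit-peak with the analytic argmax", {
  k <- kernel_params(0.014, 0.067, 0.58)
  ker <- event_kernel(k, 10000)
  expect_lte(max(ker), 1)
  expect_gt(max(ker), 1 - 1e-6)  # a 0.1 ms grid lands almost on the peak
  t_star <- kernel_peak_time(k)
  expect_equal(t_star, 0.014 * log(1 + 0.067 / 0.014))
  expect_lte(abs((which.max(ker) - 1) / 10000 - t_star), 1 / 10000)
  # dense numeric scan confirms the closed-form argmax
  tt <- seq(0, 0.5, by = 1e-5)
  expect_lte(abs(tt[which.max(oracle_kernel(tt, 0.014, 0.067))] - t_star), 1e-4)
  # tail truncated at the 1e-4 level
  expect_gte(ker[length(ker)], 1e-4)
  t_next <- length(ker) / 10000
  expect_lt(oracle_kernel_unit(t_next, 0.014, 0.067), 1e-4)
  # decay -> infinity approaches a pure saturating rise
  k2 <- event_kernel(suppressWarnings(kernel_params(0.01, 1e6, 1)), 200)
  expect_equal(k2[1:40], 1 - exp(-(0:39) / (200 * 0.01)), tolerance = 1e-3)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- scenario("synap8m", duration_s = 10, rate_hz = 1, seed = 77)
  s1 <- simulate_traces(cfg)
  s2 <- simulate_traces(cfg)
  expect_identical(trace_roi(s1$traces)$signal, trace_roi(s2$traces)$signal)
  expect_identical(s1$truth$events, s2$truth$events)
  # and the seed matters
  cfg2 <- scenario("synap8m", duration_s = 10, rate_hz = 1, seed = 78)
  expect_false(identical(trace_roi(simulate_traces(cfg2)$traces)$signal,
                         trace_roi(s1$traces)$signal))
})

test_that("poisson event counts follow the poisson law", {
  counts <- vapply(1:60, function(s) {
    cfg <- scenario("synap8m", duration_s = 60, rate_hz = 2, seed = s, fps = 20)
    nrow(simulate_traces(cfg)$truth$events)
  }, numeric(1))
  lambda <- 120
  expect_gt(mean(counts), lambda - 3 * sqrt(lambda / 60))
  expect_lt(mean(counts), lambda + 3 * sqrt(lambda / 60))
})

test_that("every ground-truth event appears in the emitted trace", {
  s <- sim_isolated("synap8m", n_ev = 30, seed = 41, noise_sd = 0)
  tr <- trace_roi(s$sim$traces)
  v <- tr$signal / 100 - 1
  pk <- detect_peaks(v, tr$time_s, detection_params(0.29, min_distance_s = 0.3))
  expect_identical(nrow(pk), nrow(s$sim$truth$events))
})

test_that("gain-corrupted dR/R equals the gain-free dF/F within 1%", {
  base <- list(duration_s = 41, seed = 6, event_model = "protocol",
               protocol = stim_protocol(times_s = (0:39) + 0.5),
               latency_mean_s = 0, latency_jitter_s = 0, noise_sd = 0)
  cfg_gain <- do.call(scenario, c(list("scar8m"), base, shared_gain_cv = 0.2))
  cfg_free <- do.call(scenario, c(list("scar8m"), base, shared_gain_cv = 0))
  sg <- simulate_traces(cfg_gain)
  sf <- simulate_traces(cfg_free)
  t <- timebase(sg$traces)
  d_g <- trace_roi(sg$traces)
  drr_gain <- drr(d_g$signal, d_g$reference, t)
  dff_free <- dff(trace_roi(sf$traces)$signal, 100, t)
  expect_lt(abs(max(drr_gain$value) - max(dff_free$value)) / max(dff_free$value),
            0.01)
})

test_that("scenarios encode the published sensor parameters", {
  s8m <- scenario("synap8m")
  expect_equal(s8m$kernel$tau_rise_s, 0.014)
  expect_equal(s8m$kernel$tau_decay_s, 0.067)
  expect_equal(s8m$kernel$amplitude_mean, 0.58)
  s6f <- scenario("synap6f")
  expect_equal(s6f$kernel$tau_rise_s, 0.021)
  expect_equal(s6f$kernel$tau_decay_s, 0.099)
  expect_equal(s6f$kernel$amplitude_mean, 0.27)
  expect_equal(s6f$detection_miss_p, 0.43)
  expect_equal(scenario("synap8f")$kernel$amplitude_mean, 0.35)
  expect_equal(scenario("scar8f")$kernel$tau_decay_s, 0.0666)
  expect_equal(scenario("scar8m")$kernel$tau_rise_s, 0.007)
  expect_equal(scenario("GluRIIA")$mepsp_mean_mv, 0.38)
  expect_equal(scenario("wt")$mepsp_mean_mv, 0.64)
  expect_equal(scenario("GluRIIB")$mepsp_mean_mv, 0.82)
  expect_error(scenario("nope"), "available", class = "synca_parameter_error")
})

test_that("paired simulations omit optical events at the miss rate", {
  cfg <- scenario("synap8m", fps = 100, duration_s = 60, seed = 53,
                  event_model = "protocol", noise_sd = 0,
                  protocol = stim_protocol(times_s = seq(0.3, 59.7, by = 0.2)),
                  latency_mean_s = 0, latency_jitter_s = 0)
  # miss_p = 0: every event present, downstream detection fraction 1
  p0 <- simulate_paired(cfg, miss_p = 0, mv_scale = 1.5)
  expect_true(all(p0$truth$events$optical_present))
  res0 <- run_match(p0$traces, p0$ephys,
                    detection_params(0.29, min_distance_s = 0.05),
                    qparams = quantify_params(smooth = FALSE))
  expect_equal(res0$match$detection_fraction, 1)
  # mv noise 0: paired amplitudes correlate perfectly
  expect_equal(res0$match$pearson_r, NA_real_)  # zero variance both sides
  # with variable amplitudes the correlation is 1
  cfgv <- cfg
  cfgv$kernel$amplitude_cv <- 0.3
  pv <- simulate_paired(cfgv, miss_p = 0, mv_scale = 1.5)
  resv <- run_match(pv$traces, pv$ephys,
                    detection_params(0.2, min_distance_s = 0.05),
                    qparams = quantify_params(smooth = FALSE))
  expect_gt(resv$match$pearson_r, 0.95)
  # a nonzero miss probability shows up in the truth table
  pm <- simulate_paired(cfg, miss_p = 0.43)
  frac <- mean(pm$truth$events$optical_present)
  expect_lt(abs(frac - 0.57), 1.96 * sqrt(0.57 * 0.43 / 300) + 0.01)
  expect_error(simulate_paired(cfg, miss_p = 1), class = "synca_parameter_error")
})
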