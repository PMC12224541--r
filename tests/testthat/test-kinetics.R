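test_that("onset search follows the 10% crossing", {
  # noise-free kernel: onset within 1 frame of the true 10%-amplitude time
  dt <- 1 / 1000
  t <- seq(0, 1, by = dt)
  v <- 0.58 * oracle_kernel_unit(t - 0.2, 0.014, 0.067)
  ip <- which.max(v)
  io <- find_onset(v, ip)
  true_cross <- t[min(which(v >= 0.1 * v[ip]))]
  expect_lte(abs(t[io] - true_cross), 2 * dt)
  # step event: onset is the sample before the peak
  vstep <- c(rep(0, 10), rep(1, 5), rep(0, 10))
  expect_identical(find_onset(vstep, 11L), 10L)
  # event truncated at the recording start has no onset
  expect_true(is.na(find_onset(v[ip:length(v)], 1L)))
})

test_that("decay fit recovers a pure exponential to solver precision", {
  t <- seq(0, 0.5, by = 1 / 1000)
  y <- 2 * exp(-t / 0.1)
  fd <- fit_decay(y, t, 1L)
  expect_equal(fd$flag, "ok")
  expect_equal(fd$tau_decay_s, 0.1, tolerance = 1e-6)
  expect_equal(fd$y_peak_fit, 2, tolerance = 1e-6)
  expect_gt(fd$r2, 1 - 1e-9)
})

test_that("unfittable decays flag instead of crashing", {
  t <- seq(0, 1, by = 0.01)
  flat <- fit_decay(rep(2, length(t)), t, 5L)
  expect_true(flat$flag %in% c("fit_failed", "insufficient_data"))
  expect_true(is.na(flat$tau_decay_s))
  short <- fit_decay(c(1, 0.5, 0.2), c(0, 0.01, 0.02), 1L)
  expect_equal(short$flag, "insufficient_data")
})

test_that("decay fit is robust to 5% gaussian noise in the median", {
  set.seed(21)
  t <- seq(0, 0.6, by = 1 / 1000)
  taus <- vapply(1:100, function(i) {
    y <- 1 * exp(-t / 0.08) + rnorm(length(t), 0, 0.05)
    fit_decay(y, t, 1L)$tau_decay_s
  }, numeric(1))
  expect_lt(abs(median(taus, na.rm = TRUE) - 0.08) / 0.08, 0.05)
})

test_that("rise fit recovers a pure saturating exponential", {
  dt <- 1 / 1000
  t <- seq(0, 0.1, by = dt)
  y <- 1 * (1 - exp(-t / 0.014))
  ip <- length(y)
  fr <- fit_rise(y, t, 1L, ip)
  expect_equal(fr$flag, "ok")
  expect_equal(fr$tau_rise_s, 0.014, tolerance = 1e-4)
  # two samples between onset and peak are not enough
  expect_equal(fit_rise(y, t, 1L, 2L)$flag, "rise_unfittable")
})

test_that("decay-compensated rise fit is accurate at 1 kHz and flagged near the frame limit", {
  # 1 kHz: model-faithful recovery
  t <- seq(0, 1.5, by = 1 / 1000)
  v <- oracle_kernel_unit(t - 0.2, 0.007, 0.0992)
  ip <- which.max(v)
  io <- find_onset(v, ip)
  fd <- fit_decay(v, t, ip)
  fr <- fit_rise(v, t, io, ip, fd$tau_decay_s)
  expect_lt(abs(fr$tau_rise_s - 0.007) / 0.007, 0.02)
  # 115 fps: 14 ms rise is ~1.6 frames; biased < 30% and flagged
  t2 <- seq(0, 1.5, by = 1 / 115)
  v2 <- oracle_kernel_unit(t2 - 0.2, 0.014, 0.067)
  ip2 <- which.max(v2)
  io2 <- find_onset(v2, ip2)
  fd2 <- fit_decay(v2, t2, ip2)
  fr2 <- fit_rise(v2, t2, io2, ip2, fd2$tau_decay_s)
  expect_lt(abs(fr2$tau_rise_s - 0.014) / 0.014, 0.3)
  expect_equal(fr2$flag, "near_resolution")
})

test_that("quantified events carry exact noise-free amplitudes", {
  k <- kernel_params(0.014, 0.067, 0.58)
  dt <- 1 / 115
  ev_t <- 230 * dt - kernel_peak_time(k)
  cfg <- sim_config(fps = 115, duration_s = 6, kernel = k,
                    event_model = "protocol",
                    protocol = stim_protocol(times_s = ev_t),
                    latency_mean_s = 0, latency_jitter_s = 0,
                    noise_sd = 0, seed = 1)
  tr <- trace_roi(simulate_traces(cfg)$traces)
  v <- tr$signal / 100 - 1
  pk <- detect_peaks(v, tr$time_s, detection_params(0.29))
  ev <- quantify_events(v, pk, quantify_params(smooth = FALSE), time = tr$time_s)
  expect_equal(ev$amplitude, 0.58, tolerance = 1e-9)
  expect_equal(ev$provenance, "auto")
})

test_that("sum_df scales linearly with amplitude and grows with tau_decay", {
  dt <- 1 / 115
  t <- seq(0, 5, by = dt)
  ev <- function(a, td) {
    v <- a * oracle_kernel_unit(t - 1, 0.014, td)
    pk <- detect_peaks(v, t, detection_params(a / 2))
    quantify_events(v, pk, quantify_params(smooth = FALSE), time = t)
  }
  e1 <- ev(0.3, 0.067)
  e2 <- ev(0.6, 0.067)
  expect_equal(e2$sum_df / e1$sum_df, 2, tolerance = 1e-6)
  sums <- vapply(c(0.04, 0.08, 0.16), function(td) ev(0.5, td)$sum_df, numeric(1))
  expect_true(all(diff(sums) > 0))
})

test_that("snr reflects the baseline noise level", {
  set.seed(31)
  dt <- 1 / 115
  t <- seq(0, 60, by = dt)
  v <- oracle_kernel_unit(t - 30, 0.014, 0.067) + rnorm(length(t), 0, 0.1)
  pk <- detect_peaks(smooth_trace(v), t,
                     detection_params(0.5, min_distance_s = 0.5))
  ev <- quantify_events(v, pk, time = t)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$snr, ev$amplitude / 0.1, tolerance = 0.1)
})

test_that("noise-free parameter recovery is within 1% at >=10 samples per tau", {
  t <- seq(0, 3, by = 1 / 1000)
  for (p in list(c(0.007, 0.0992), c(0.0053, 0.0666))) {
    v <- 0.9 * oracle_kernel_unit(t - 0.5, p[1], p[2])
    pk <- detect_peaks(v, t, detection_params(0.45))
    ev <- quantify_events(v, pk, quantify_params(smooth = FALSE), time = t)
    expect_lt(abs(ev$tau_decay_s - p[2]) / p[2], 0.01)
    expect_lt(abs(ev$tau_rise_s - p[1]) / p[1], 0.01)
  }
})
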