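test_that("degenerate traces yield no peaks", {
  p <- detection_params(0.1)
  expect_identical(nrow(detect_peaks(rep(0, 100), params = p)), 0L)
  expect_identical(nrow(detect_peaks(seq(0, 1, length.out = 50), params = p)), 0L)
})

test_that("a single kernel is found at its argmax", {
  t <- seq(0, 2, by = 1 / 115)
  v <- oracle_kernel_unit(t - 0.5, 0.014, 0.067)
  pk <- detect_peaks(v, t, detection_params(0.5))
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$index, which.max(v))
  expect_identical(pk$provenance, "auto")
})

test_that("the distance filter keeps the higher of two close peaks", {
  t <- seq(0, 1, by = 1 / 200)
  v <- 0.8 * oracle_kernel_unit(t - 0.40, 0.005, 0.03) +
    1.0 * oracle_kernel_unit(t - 0.43, 0.005, 0.03)
  pk <- detect_peaks(v, t, detection_params(0.3, min_distance_s = 0.05))
  expect_identical(nrow(pk), 1L)
  oracle <- oracle_detect(v, t, 0.3, min_distance_s = 0.05)
  expect_identical(pk$index, as.integer(oracle))
  # without the distance constraint, both local maxima qualify
  expect_identical(nrow(detect_peaks(v, t, detection_params(0.3))), 2L)
})

test_that("raising the threshold never increases the peak count", {
  set.seed(7)
  t <- seq(0, 5, by = 0.01)
  v <- abs(rnorm(length(t), 0, 0.3))
  counts <- vapply(seq(0.05, 1.2, by = 0.05), function(thr) {
    nrow(detect_peaks(v, t, detection_params(thr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection equals the brute-force oracle on random traces", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(20:400, 1)
    v <- cumsum(rnorm(n))
    v <- v - min(v) + runif(1)
    if (rep %% 3 == 0) v <- round(v, 1)  # force plateaus and ties
    t <- (seq_len(n) - 1) * 0.01
    thr <- quantile(v, runif(1, 0.3, 0.9), names = FALSE)
    md <- sample(c(0, 0.02, 0.05, 0.1), 1)
    mw <- sample(c(0, 0.01, 0.03), 1)
    got <- detect_peaks(v, t, detection_params(thr, min_width_s = mw,
                                               min_distance_s = md))
    want <- oracle_detect(v, t, thr, min_width_s = mw, min_distance_s = md)
    expect_identical(got$index, as.integer(want))
  }
})

test_that("plateau peaks report their first sample and bounds are excluded", {
  v <- c(5, 1, 2, 2, 2, 1, 9)  # ends high: boundary is not a peak
  pk <- detect_peaks(v, params = detection_params(0.5))
  expect_identical(pk$index, 3L)
})

test_that("nearest_peak resolves clicks like a manual selection", {
  t <- seq(0, 2, by = 0.01)
  v <- oracle_kernel_unit(t - 0.95, 0.005, 0.02) +
    0.4 * oracle_kernel_unit(t - 1.15, 0.005, 0.02)
  m1 <- which(t >= 0.95 & t <= 1.05)[which.max(v[t >= 0.95 & t <= 1.05])]
  # single maximum case
  v1 <- oracle_kernel_unit(t - 1.0, 0.01, 0.05)
  p <- nearest_peak(v1, t, t_query = 0.9, search_window_s = 0.5)
  expect_equal(p$time_s, t[which.max(v1)])
  expect_identical(p$provenance, "manual")
  # two maxima: nearest wins on each side of the midpoint
  tm <- c(t[oracle_local_maxima(v)])
  expect_equal(nearest_peak(v, t, 1.09 - (1.09 - tm[1]) * 0, 0.5)$time_s,
               tm[which.min(abs(tm - 1.09))])
  expect_equal(nearest_peak(v, t, 1.11, 0.5)$time_s,
               tm[which.min(abs(tm - 1.11))])
  # monotonic ramp has no interior maximum
  expect_error(nearest_peak(seq(0, 1, length.out = 100), t[1:100], 0.5, 0.3),
               class = "synca_not_found")
})

test_that("edit_events adds, deduplicates and removes deterministically", {
  t <- seq(0, 3, by = 0.01)
  v <- oracle_kernel_unit(t - 0.5, 0.01, 0.05) +
    0.2 * oracle_kernel_unit(t - 1.5, 0.01, 0.05)
  auto <- detect_peaks(v, t, detection_params(0.5))
  expect_identical(nrow(auto), 1L)
  # add the sub-threshold event
  ed <- edit_events(auto, add = 1.5, values = v, time = t)
  expect_identical(nrow(ed), 2L)
  expect_identical(ed$provenance[ed$time_s > 1], "manual")
  # idempotent add
  ed2 <- edit_events(ed, add = 1.51, values = v, time = t)
  expect_identical(nrow(ed2), 2L)
  # remove all
  ed3 <- edit_events(ed2, remove = c(0.52, 1.52), values = v, time = t)
  expect_identical(nrow(ed3), 0L)
  expect_error(edit_events(ed2, remove = 2.9, values = v, time = t, window_s = 0.2),
               "2.9", class = "synca_not_found")
})

test_that("noise-free detection has perfect precision and recall", {
  s <- sim_isolated("synap8m", n_ev = 25, seed = 4, noise_sd = 0)
  tr <- trace_roi(s$sim$traces)
  v <- tr$signal / 100 - 1
  pk <- detect_peaks(v, tr$time_s, detection_params(0.29, min_distance_s = 0.3))
  truth <- s$sim$truth$events$time_s + oracle_kernel_peak_t(0.014, 0.067)
  expect_identical(nrow(pk), length(truth))
  expect_true(all(abs(pk$time_s - truth) <= 2 / 115))
})
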