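#' Baseline estimation settings
#'
#' Two estimators are provided. `prestimulus_mean` uses the mean of the
#' samples in the window `[0, window_s)` — appropriate for evoked
#' recordings where the window precedes the first stimulus.
#' `rolling_percentile` tracks a low percentile of the trace in a centered
#' rolling window (edges handled by replicating the first/last sample) —
#' appropriate for long spontaneous-event recordings with slow drift.
#'
#' @param method `"prestimulus_mean"` or `"rolling_percentile"`.
#' @param window_s Window length in seconds (> 0). Defaults: 0.5 s for
#'   `prestimulus_mean`, 2 s for `rolling_percentile`.
#' @param percentile Fraction in (0, 1); rolling method only (default 0.1).
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(method = c("prestimulus_mean", "rolling_percentile"),
                          window_s = NULL, percentile = 0.1) {
  method <- match.arg(method)
  window_s <- window_s %||% if (method == "prestimulus_mean") 0.5 else 2
  if (!is.numeric(window_s) || window_s <= 0) {
    stop_synca("`window_s` must be > 0", "parameter_error")
  }
  if (method == "rolling_percentile" && (percentile <= 0 || percentile >= 1)) {
    stop_synca("`percentile` must be in (0, 1)", "parameter_error")
  }
  structure(list(method = method, window_s = window_s, percentile = percentile),
            class = "baseline_spec")
}

#' Estimate a baseline series for an intensity trace
#'
#' @param x Numeric intensity (or ratio) series.
#' @param time Seconds, same length as `x`.
#' @param spec A [baseline_spec()].
#' @return Numeric baseline series, same length as `x`, strictly positive.
#' @export
estimate_baseline <- function(x, time, spec = baseline_spec()) {
  if (length(x) != length(time)) stop_synca("length mismatch", "format_error")
  if (spec$method == "prestimulus_mean") {
    idx <- which(time < time[1] + spec$window_s)
    if (length(idx) < 4) {
      stop_synca("baseline window covers fewer than 4 samples", "insufficient_data")
    }
    b <- rep(mean(x[idx]), length(x))
  } else {
    dt <- median(diff(time))
    w <- max(4L, round(spec$window_s / dt))
    if (w > length(x)) w <- length(x)
    if (length(x) < 4) stop_synca("baseline window covers fewer than 4 samples", "insufficient_data")
    half <- w %/% 2
    padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
    b <- vapply(seq_along(x), function(i) {
      quantile(padded[i:(i + 2 * half)], probs = spec$percentile, names = FALSE)
    }, numeric(1))
  }
  if (any(b <= 0)) {
    stop_synca("estimated baseline is not strictly positive; ROI unusable", "baseline_error")
  }
  b
}

new_norm_trace <- function(time, values, mode, baseline, spec, roi = NA_character_) {
  if (any(values < -1)) {
    stop_synca("normalized values below -1 indicate a baseline error", "baseline_error")
  }
  structure(
    tibble(time_s = time, value = values),
    class = c("norm_trace", class(tibble())),
    mode = mode, baseline = baseline,
    baseline_method = if (is.null(spec)) "given" else spec$method,
    roi = roi
  )
}

#' Fractional fluorescence change (dF/F)
#'
#' `values_i = (F_i - F0_i) / F0_i`. Negative excursions below baseline are
#' legal; values below -1 (impossible for a correct positive baseline)
#' raise a baseline error.
#'
#' @param x Intensity series.
#' @param baseline Baseline series or scalar F0, strictly positive.
#' @param time Seconds; defaults to sample index.
#' @param roi Optional ROI id carried on the result.
#' @return A `norm_trace`: tibble with `time_s`, `value` and attributes
#'   `mode = "dff"`, `baseline`.
#' @export
dff <- function(x, baseline, time = seq_along(x) - 1, roi = NA_character_) {
  if (length(baseline) == 1) baseline <- rep(baseline, length(x))
  if (any(baseline <= 0)) stop_synca("baseline must be strictly positive", "baseline_error")
  new_norm_trace(time, (x - baseline) / baseline, "dff", baseline, NULL, roi)
}

#' Ratiometric fractional change (dR/R)
#'
#' Forms the per-frame ratio `r_i = G_i / R_i` of the Ca2+-sensitive to the
#' Ca2+-insensitive channel, baselines the ratio (not the channels), and
#' returns `(r_i - R0_i) / R0_i`. Because the ratio is taken first, any
#' shared multiplicative gain (illumination flicker, focus drift) cancels
#' exactly.
#'
#' @param signal Ca2+-sensitive intensity series.
#' @param reference Ca2+-insensitive intensity series, strictly positive.
#' @param time Seconds.
#' @param spec [baseline_spec()] applied to the ratio series.
#' @param roi Optional ROI id.
#' @return A `norm_trace` with `mode = "drr"`.
#' @export
drr <- function(signal, reference, time = seq_along(signal) - 1,
                spec = baseline_spec(), roi = NA_character_) {
  if (length(signal) != length(reference)) stop_synca("length mismatch", "format_error")
  if (any(reference <= 0)) {
    stop_synca("reference channel must be strictly positive", "reference_error")
  }
  r <- signal / reference
  r0 <- estimate_baseline(r, time, spec)
  new_norm_trace(time, (r - r0) / r0, "drr", r0, spec, roi)
}

#' Normalize every ROI of a trace set
#'
#' Applies [dff()] (single-channel) or [drr()] (two-channel) per ROI and
#' returns one long tibble.
#'
#' @param trace A [trace_set()].
#' @param mode `"dff"` or `"drr"`; default `"drr"` when a reference channel
#'   is present.
#' @param spec [baseline_spec()].
#' @return Tibble with columns `roi`, `time_s`, `value` and attribute
#'   `mode`.
#' @export
normalize_traces <- function(trace, mode = NULL, spec = baseline_spec()) {
  has_ref <- "reference" %in% names(trace)
  mode <- mode %||% if (has_ref) "drr" else "dff"
  if (mode == "drr" && !has_ref) {
    stop_synca("drr requires a reference channel", "reference_error")
  }
  t <- timebase(trace)
  out <- purrr::map_dfr(trace_rois(trace), function(r) {
    d <- trace_roi(trace, r)
    nt <- if (mode == "drr") {
      drr(d$signal, d$reference, t, spec, roi = r)
    } else {
      f0 <- estimate_baseline(d$signal, t, spec)
      dff(d$signal, f0, t, roi = r)
    }
    tibble(roi = r, time_s = nt$time_s, value = nt$value)
  })
  attr(out, "mode") <- mode
  out
}

#' Refine a normalized baseline from event-free samples
#'
#' A low-percentile first-pass baseline sits below the true baseline by a
#' noise-dependent offset (the percentile of the noise distribution),
#' which inflates normalized amplitudes and leaves a DC offset under decay
#' tails. Given the detected events, this second pass estimates the
#' residual baseline `b(t)` as the rolling mean of the *event-free*
#' samples (unbiased under zero-mean noise) and re-references the trace:
#' `value' = (value - b) / (1 + b)`, which is exactly the dF/F (or dR/R)
#' that the corrected baseline `F0 * (1 + b)` would have produced.
#'
#' @param values Normalized trace values.
#' @param time Seconds.
#' @param peaks Peak tibble from [detect_peaks()] (first pass).
#' @param window_s Rolling-mean window (s).
#' @param pad_pre_s,pad_post_s Mask half-widths around each peak (s);
#'   `pad_post_s` should cover the slowest decay tail.
#' @return Re-referenced values, same length.
#' @export
rebaseline_eventfree <- function(values, time, peaks, window_s = 4,
                                 pad_pre_s = 0.15, pad_post_s = 0.6) {
  n <- length(values)
  dt <- median(diff(time))
  make_mask <- function(pre, post) {
    m <- rep(FALSE, n)
    for (tp in peaks$time_s) m[time >= tp - pre & time <= tp + post] <- TRUE
    m
  }
  mask <- make_mask(pad_pre_s, pad_post_s)
  # dense recordings: shrink the pads until some trace is left event-free
  while (all(mask) && pad_post_s > 4 * dt) {
    pad_pre_s <- pad_pre_s / 2
    pad_post_s <- pad_post_s / 2
    mask <- make_mask(pad_pre_s, pad_post_s)
  }
  if (all(mask)) return(values)  # nothing event-free to estimate from
  w <- max(4L, as.integer(round(window_s / dt)))
  half <- w %/% 2
  inc <- as.numeric(!mask)
  cs_x <- cumsum(c(0, values * inc))
  cs_n <- cumsum(c(0, inc))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- cs_n[hi + 1] - cs_n[lo]
  b <- ifelse(cnt > 0, (cs_x[hi + 1] - cs_x[lo]) / cnt, NA_real_)
  if (anyNA(b)) {
    ok <- which(!is.na(b))
    b <- stats::approx(ok, b[ok], xout = seq_len(n), rule = 2)$y
  }
  (values - b) / (1 + b)
}

#' Photobleaching correction (opt-in)
#'
#' Fits `b(t) = b0 * exp(-t / tau_b)` to an event-masked copy of the trace
#' (samples above median + 3 * MAD are excluded) and rescales by
#' `b(0) / b(t)`. The trace is returned unchanged, with a flag, when no
#' appreciable bleach is found (fitted `tau_b` longer than 10x the
#' recording) or the fit fails; the input is never silently altered.
#'
#' @param x Intensity series (>= 10 samples).
#' @param time Seconds.
#' @return List with `values` (corrected series), `tau_bleach_s` (or `NA`)
#'   and `flag` (`"ok"`, `"no_bleach"` or `"fit_failed"`).
#' @export
bleach_correct <- function(x, time) {
  if (length(x) < 10) stop_synca("need at least 10 samples", "insufficient_data")
  mask <- x <= median(x) + 3 * stats::mad(x)
  if (sum(mask) < 10) mask <- rep(TRUE, length(x))
  xm <- x[mask]; tm <- time[mask]
  dur <- max(time) - min(time)
  fit <- try(minpack.lm::nlsLM(
    xm ~ b0 * exp(-tm / tau),
    start = list(b0 = xm[1], tau = dur),
    lower = c(1e-12, 1e-6), upper = c(Inf, 1000 * dur),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(values = x, tau_bleach_s = NA_real_, flag = "fit_failed"))
  }
  cf <- coef(fit)
  if (cf[["tau"]] > 10 * dur) {
    return(list(values = x, tau_bleach_s = cf[["tau"]], flag = "no_bleach"))
  }
  b <- exp(-time / cf[["tau"]])
  list(values = x / b, tau_bleach_s = cf[["tau"]], flag = "ok")
}
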