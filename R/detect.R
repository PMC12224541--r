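#' Peak-detection parameters
#'
#' @param threshold_amplitude Minimum peak height in normalized (dF/F or
#'   dR/R) units, > 0.
#' @param min_width_s Minimum half-prominence width in seconds (>= 0;
#'   0 disables the width filter).
#' @param min_distance_s Minimum inter-peak distance in seconds (>= 0).
#'   When two qualifying peaks are closer, the higher is kept (tie: the
#'   earlier).
#' @param prominence Optional minimum topographic prominence.
#' @return A `detection_params` list.
#' @export
detection_params <- function(threshold_amplitude, min_width_s = 0,
                             min_distance_s = 0, prominence = NULL) {
  if (threshold_amplitude <= 0) stop_synca("`threshold_amplitude` must be > 0", "parameter_error")
  if (min_width_s < 0 || min_distance_s < 0) {
    stop_synca("widths/distances must be >= 0", "parameter_error")
  }
  structure(
    list(threshold_amplitude = threshold_amplitude, min_width_s = min_width_s,
         min_distance_s = min_distance_s, prominence = prominence),
    class = "detection_params"
  )
}

# strict local maxima; plateaus report their first sample; boundary samples
# are never peaks
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Topographic prominence and half-prominence width (seconds) of the peak at
# index ip. Bases: on each side, scan away from the peak until a sample
# strictly higher than the peak (or the trace edge); the base is the lowest
# sample in that range. prominence = height - max(left_base, right_base).
# Width: the measurement level is height - prominence/2; on each side the
# crossing position is found by linear interpolation between the last
# sample above the level and the first at-or-below it, bounded by the base
# position. The level always lies at or above both bases, so a crossing
# exists on both sides.
peak_prominence_width <- function(v, time, ip) {
  n <- length(v)
  h <- v[ip]
  il <- ip
  i <- ip - 1L
  while (i >= 1L && v[i] <= h) {
    if (v[i] < v[il]) il <- i
    i <- i - 1L
  }
  if (il == ip) il <- max(1L, ip - 1L)
  ir <- ip
  i <- ip + 1L
  while (i <= n && v[i] <= h) {
    if (v[i] < v[ir]) ir <- i
    i <- i + 1L
  }
  if (ir == ip) ir <- min(n, ip + 1L)
  prom <- h - max(v[il], v[ir])
  level <- h - prom / 2
  cross <- function(from, to) {
    step <- if (to < from) -1L else 1L
    prev <- from
    for (i in seq(from + step, to, by = step)) {
      if (v[i] <= level) {
        if (v[i] == level || v[prev] == v[i]) return(time[i])
        frac <- (v[prev] - level) / (v[prev] - v[i])
        return(time[prev] + frac * (time[i] - time[prev]))
      }
      prev <- i
    }
    time[to]
  }
  xl <- if (il == ip) time[ip] else cross(ip, il)
  xr <- if (ir == ip) time[ip] else cross(ip, ir)
  list(prominence = prom, width_s = xr - xl)
}

# greedy keep-highest distance filter; tie -> earlier time
enforce_min_distance <- function(idx, heights, times, min_distance_s) {
  if (min_distance_s <= 0 || length(idx) < 2) return(idx)
  ord <- order(-heights, times)
  kept <- integer(0)
  for (k in ord) {
    if (!length(kept) || all(abs(times[k] - times[kept]) >= min_distance_s)) {
      kept <- c(kept, k)
    }
  }
  sort(idx[kept])
}

#' Detect candidate peaks in a normalized trace
#'
#' Finds all strict local maxima (plateaus report their first sample;
#' boundary samples are excluded) with height at least
#' `threshold_amplitude`, half-prominence width at least `min_width_s`,
#' and pairwise spacing at least `min_distance_s` (resolved greedily,
#' keeping the higher peak; ties keep the earlier). Deterministic: the
#' same input always yields the same output.
#'
#' @param values Normalized trace values (a `norm_trace`, or a bare
#'   numeric vector).
#' @param time Seconds; taken from the `norm_trace` when omitted.
#' @param params A [detection_params()].
#' @return Tibble of candidate peaks: `index` (1-based frame), `time_s`,
#'   `height`, `provenance = "auto"`, sorted by time. Zero rows when
#'   nothing qualifies.
#' @export
detect_peaks <- function(values, time = NULL, params) {
  if (inherits(values, "norm_trace")) {
    time <- time %||% values$time_s
    values <- values$value
  }
  if (is.null(time)) time <- seq_along(values) - 1
  if (!all(is.finite(values))) stop_synca("values must be finite", "format_error")
  cand <- local_maxima(values)
  cand <- cand[values[cand] >= params$threshold_amplitude]
  if (!is.null(params$prominence) || params$min_width_s > 0) {
    pw <- purrr::map(cand, ~ peak_prominence_width(values, time, .x))
    ok <- purrr::map_lgl(pw, function(p) {
      (is.null(params$prominence) || p$prominence >= params$prominence) &&
        p$width_s >= params$min_width_s
    })
    cand <- cand[ok]
  }
  cand <- enforce_min_distance(cand, values[cand], time[cand], params$min_distance_s)
  tibble(
    index = as.integer(cand), time_s = time[cand], height = values[cand],
    provenance = rep("auto", length(cand))
  )
}

#' Find the local maximum nearest a queried time
#'
#' Programmatic equivalent of click-to-select: returns the local maximum
#' nearest in time to `t_query` within `+/- search_window_s`. No threshold
#' is applied; the result is marked `provenance = "manual"`. Ties (equal
#' distance) resolve to the earlier peak.
#'
#' @inheritParams detect_peaks
#' @param t_query Query time in seconds.
#' @param search_window_s Half-width of the search window in seconds.
#' @return One-row peak tibble.
#' @export
nearest_peak <- function(values, time = NULL, t_query, search_window_s = 0.5) {
  if (inherits(values, "norm_trace")) {
    time <- time %||% values$time_s
    values <- values$value
  }
  if (is.null(time)) time <- seq_along(values) - 1
  lm <- local_maxima(values)
  lm <- lm[abs(time[lm] - t_query) <= search_window_s]
  if (!length(lm)) {
    stop_synca(sprintf("no local maximum within %.3g s of t = %.3g s",
                       search_window_s, t_query), "not_found")
  }
  d <- abs(time[lm] - t_query)
  ip <- lm[order(d, time[lm])][1]
  tibble(index = as.integer(ip), time_s = time[ip], height = values[ip],
         provenance = "manual")
}

#' Apply manual corrections to a peak list
#'
#' Each `add` time is resolved to its nearest local maximum via
#' [nearest_peak()] and inserted unless a peak at that index already
#' exists (idempotent). Each `remove` time deletes the nearest existing
#' peak within `window_s`; a remove with no peak in range is an error that
#' names the offending time.
#'
#' @param peaks Peak tibble from [detect_peaks()].
#' @param add,remove Numeric vectors of times (seconds).
#' @inheritParams nearest_peak
#' @param window_s Search half-window in seconds for both operations.
#' @return Corrected peak tibble, sorted by time, unique indices.
#' @export
edit_events <- function(peaks, add = numeric(0), remove = numeric(0),
                        values = NULL, time = NULL, window_s = 0.5) {
  for (tr in remove) {
    if (!nrow(peaks)) stop_synca(sprintf("no peak within %.3g s of t = %.3g s to remove",
                                         window_s, tr), "not_found")
    d <- abs(peaks$time_s - tr)
    if (min(d) > window_s) {
      stop_synca(sprintf("no peak within %.3g s of t = %.3g s to remove", window_s, tr),
                 "not_found")
    }
    peaks <- peaks[-which.min(d), ]
  }
  for (ta in add) {
    p <- nearest_peak(values, time, ta, window_s)
    if (!p$index %in% peaks$index) peaks <- bind_rows(peaks, p)
  }
  arrange(distinct(peaks, .data$index, .keep_all = TRUE), .data$time_s)
}

#' Savitzky-Golay smoothed copy of a trace
#'
#' Quadratic Savitzky-Golay smoothing (default window 5) preserves peak
#' height to second order while averaging frame noise; the pipelines use
#' it for peak location, amplitude measurement and fit-window placement
#' (kinetic fits always run on the raw samples).
#'
#' @param values Numeric series.
#' @param n Odd window length (samples).
#' @param p Polynomial order.
#' @return Smoothed numeric series, same length.
#' @export
smooth_trace <- function(values, n = 5, p = 2) {
  if (length(values) <= n) return(values)
  as.numeric(signal::sgolayfilt(values, p = p, n = n))
}
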