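#' Event quantification settings
#'
#' @param onset_fraction Fraction of the peak amplitude defining event
#'   onset (default 0.1: onset is the last pre-peak sample below 10% of
#'   the amplitude).
#' @param decay_return_fraction Fraction of the amplitude defining the end
#'   of the event window for integration and the first-pass decay window
#'   (default 0.1).
#' @param smooth Use a Savitzky-Golay smoothed copy of the trace for peak
#'   amplitude measurement, onset search and fit-window placement (fits
#'   always run on raw samples). Default `TRUE`; disable for noise-free
#'   closed-form checks.
#' @param sg_n Savitzky-Golay window length (odd, samples).
#' @return A `quantify_params` list.
#' @export
quantify_params <- function(onset_fraction = 0.1, decay_return_fraction = 0.1,
                            smooth = TRUE, sg_n = 5) {
  if (onset_fraction <= 0 || onset_fraction >= 1) {
    stop_synca("`onset_fraction` must be in (0, 1)", "parameter_error")
  }
  structure(list(onset_fraction = onset_fraction,
                 decay_return_fraction = decay_return_fraction,
                 smooth = smooth, sg_n = sg_n),
            class = "quantify_params")
}

#' Locate the onset of an event
#'
#' The onset is the latest sample before the peak at which the trace is
#' still below `onset_fraction * amplitude` above the local baseline (the
#' trace stays at or above that level from the next sample to the peak).
#' For an instantaneous (step) rise this is `peak_index - 1`.
#'
#' @param values Trace values (ideally lightly smoothed for noisy data).
#' @param peak_index 1-based peak sample.
#' @param onset_fraction Fraction in (0, 1).
#' @param local_baseline Baseline level of the event (0 for a properly
#'   baselined normalized trace).
#' @param search_start Earliest sample to consider (e.g. just past the
#'   previous event).
#' @return Onset index, or `NA_integer_` when no crossing exists before
#'   the peak (event truncated at the recording start).
#' @export
find_onset <- function(values, peak_index, onset_fraction = 0.1,
                       local_baseline = 0, search_start = 1L) {
  amp <- values[peak_index] - local_baseline
  level <- local_baseline + onset_fraction * amp
  i <- peak_index - 1L
  while (i >= search_start) {
    if (values[i] < level) return(as.integer(i))
    i <- i - 1L
  }
  NA_integer_
}

lm_fit <- function(formula, data, start, lower, upper) {
  fit <- try(minpack.lm::nlsLM(
    formula, data = data, start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12, ptol = 1e-12)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) NULL else fit
}

r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst <= .Machine$double.eps) return(NA_real_)
  max(0, min(1, 1 - sum((obs - pred)^2) / sst))
}

#' Fit the exponential decay of an event
#'
#' Fits `y(t) = y_peak * exp(-t / tau_decay)` (t re-zeroed at the peak) by
#' Levenberg-Marquardt least squares. The first pass uses the window from
#' just after the peak to the first return below
#' `decay_return_fraction * amplitude`; two refinement passes then re-fit
#' on `[peak + 0.8 * tau_hat, peak + 4 * tau_hat]`, which excludes the
#' near-peak region where the rising phase of the underlying transient
#' still distorts the tail. Windows are always capped at `seg_end` (the
#' next event's onset or the trace end).
#'
#' @param values Raw trace values.
#' @param time Seconds.
#' @param peak_index 1-based peak sample.
#' @param seg_end Last sample of the event's segment.
#' @param smoothed Optional smoothed copy used for amplitude/window
#'   placement; defaults to `values`.
#' @param decay_return_fraction See [quantify_params()].
#' @return List: `tau_decay_s`, `y_peak_fit`, `r2`, `flag` (`"ok"`,
#'   `"fit_failed"`, `"insufficient_data"`), `window` (first/last sample).
#' @export
fit_decay <- function(values, time, peak_index, seg_end = length(values),
                      smoothed = NULL, decay_return_fraction = 0.1) {
  ys <- smoothed %||% values
  ip <- peak_index
  amp <- ys[ip]
  dt <- median(diff(time))
  failed <- list(tau_decay_s = NA_real_, y_peak_fit = NA_real_, r2 = NA_real_,
                 flag = "fit_failed", window = c(NA_integer_, NA_integer_))
  if (amp <= 0) return(failed)
  j <- which(ys[ip:seg_end] < decay_return_fraction * amp)[1]
  i1 <- if (is.na(j)) seg_end else ip + j - 1L
  i0 <- min(ip + 1L, seg_end)
  if (i1 - i0 + 1L < 4L) {
    i1 <- min(seg_end, i0 + 4L)
    if (i1 - i0 + 1L < 4L) {
      failed$flag <- "insufficient_data"
      return(failed)
    }
  }
  dur <- time[length(time)] - time[1]
  tau0 <- max((time[i1] - time[ip]) / log(1 / max(decay_return_fraction, 1e-3)), dt)
  cf <- NULL
  for (pass in 1:3) {
    d <- list(tt = time[i0:i1] - time[ip], yy = values[i0:i1])
    fit <- lm_fit(yy ~ a * exp(-tt / tau), d,
                  start = list(a = if (is.null(cf)) amp else cf[["a"]],
                               tau = if (is.null(cf)) tau0 else cf[["tau"]]),
                  lower = c(1e-12, dt / 100), upper = c(Inf, 100 * dur))
    if (is.null(fit)) return(failed)
    cf <- coef(fit)
    if (cf[["tau"]] >= 100 * dur * (1 - 1e-9) || cf[["tau"]] <= dt / 100 * (1 + 1e-9)) {
      return(failed)
    }
    if (pass < 3) {
      tau <- cf[["tau"]]
      i0 <- ip + max(1L, as.integer(round(0.8 * tau / dt)))
      i1 <- min(seg_end, ip + as.integer(round(4 * tau / dt)))
      if (i1 - i0 + 1L < 4L) {
        i0 <- min(ip + 1L, seg_end)
        i1 <- min(seg_end, i0 + 5L)
      }
    }
  }
  pred <- cf[["a"]] * exp(-(time[i0:i1] - time[ip]) / cf[["tau"]])
  list(tau_decay_s = cf[["tau"]], y_peak_fit = cf[["a"]],
       r2 = r_squared(values[i0:i1], pred), flag = "ok",
       window = c(as.integer(i0), as.integer(i1)))
}

#' Fit the exponential rise of an event
#'
#' Fits the rising phase with the saturating exponential
#' `y(t) = a * (1 - exp(-(t - t0) / tau_rise))`. When the event's fitted
#' decay constant is supplied, the decay that is already underway during
#' the rise is modelled explicitly: the fit becomes
#' `a * (1 - exp(-(t - t0)/tau_rise)) * exp(-(t - t0)/tau_decay)` (decay
#' constant held fixed) over a window that extends from just before the
#' onset to past the peak. Including the peak region anchors the
#' amplitude and removes the strong collinearity between the onset shift
#' `t0` and `tau_rise` that otherwise skews short-rise fits under noise.
#'
#' @param values Raw trace values.
#' @param time Seconds.
#' @param onset_index,peak_index 1-based sample indices, onset < peak.
#' @param tau_decay_s Optional fitted decay constant, held fixed in the
#'   rise model.
#' @param seg_end Last sample usable by the extended window.
#' @return List: `tau_rise_s`, `r2`, `flag` (`"ok"`, `"rise_unfittable"`,
#'   `"fit_failed"`, `"near_resolution"` when the fitted constant is
#'   shorter than two frame intervals).
#' @export
fit_rise <- function(values, time, onset_index, peak_index, tau_decay_s = NULL,
                     seg_end = length(values)) {
  failed <- list(tau_rise_s = NA_real_, r2 = NA_real_, flag = "fit_failed")
  if (is.na(onset_index) || onset_index >= peak_index) {
    failed$flag <- "rise_unfittable"
    return(failed)
  }
  if (peak_index - onset_index + 1L < 3L) {
    failed$flag <- "rise_unfittable"
    return(failed)
  }
  dt <- median(diff(time))
  span <- time[peak_index] - time[onset_index]
  # candidate starting constants: a 10-90% crossing estimate plus
  # span-based fallbacks; Levenberg-Marquardt can stall in a boundary
  # optimum from a single poor start
  rise_y <- values[onset_index:peak_index]
  tau_starts <- max(span / 2.2, dt / 4)
  cr <- try(suppressWarnings({
    t10 <- stats::approx(rise_y, time[onset_index:peak_index], 0.1 * max(rise_y),
                         ties = "ordered")$y
    t90 <- stats::approx(rise_y, time[onset_index:peak_index], 0.9 * max(rise_y),
                         ties = "ordered")$y
    (t90 - t10) / log(9)
  }), silent = TRUE)
  if (!inherits(cr, "try-error") && is.finite(cr) && cr > 0) {
    tau_starts <- c(cr, tau_starts)
  }
  tau_starts <- unique(pmax(c(tau_starts, span / 8), dt / 4))
  best_fit <- function(make_fit) {
    fits <- purrr::compact(purrr::map(tau_starts, make_fit))
    if (!length(fits)) return(NULL)
    fits[[which.min(purrr::map_dbl(fits, stats::deviance))]]
  }
  if (!is.null(tau_decay_s) && is.finite(tau_decay_s)) {
    w <- max(1L, onset_index - as.integer(ceiling(0.01 / dt))):
      min(seg_end, peak_index + as.integer(round(2 * span / dt)))
    tt <- time[w] - time[onset_index]
    yy <- values[w]
    td <- tau_decay_s
    fit <- best_fit(function(tau0) {
      ts0 <- tau0 * log(1 + td / tau0)
      a0 <- max(yy) / ((1 - exp(-ts0 / tau0)) * exp(-ts0 / td))
      lm_fit(
        yy ~ a * (1 - exp(-(tt - t0) / tau)) * exp(-(tt - t0) / td) * (tt > t0),
        list(tt = tt, yy = yy, td = td),
        start = list(a = a0, tau = tau0, t0 = -dt),
        lower = c(1e-12, dt / 100, -2 * span - dt),
        upper = c(Inf, 100 * span, 0.5 * span)
      )
    })
  } else {
    w <- onset_index:peak_index
    tt <- time[w] - time[onset_index]
    yy <- values[w]
    fit <- best_fit(function(tau0) {
      lm_fit(yy ~ a * (1 - exp(-(tt - t0) / tau)), list(tt = tt, yy = yy),
             start = list(a = max(yy), tau = tau0, t0 = -dt),
             lower = c(1e-12, dt / 100, -10 * span),
             upper = c(Inf, 100 * span, 0.9 * dt))
    })
  }
  if (is.null(fit)) return(failed)
  cf <- coef(fit)
  if (cf[["tau"]] >= 100 * span * (1 - 1e-9)) return(failed)
  flag <- if (cf[["tau"]] < 2 * dt) "near_resolution" else "ok"
  list(tau_rise_s = cf[["tau"]], r2 = r_squared(yy, predict(fit)), flag = flag)
}

#' Quantify one detected event
#'
#' Assembles the full event record: measured peak amplitude (on the
#' smoothed trace, relative to `local_baseline`), onset, decay and rise
#' fits, the integrated response `sum_df` (trapezoidal integral of the
#' raw normalized trace over the onset-to-return window), and SNR
#' (amplitude over the SD of the event-free portion of the trace).
#'
#' @param values,time Raw normalized trace and its time base.
#' @param peak One-row peak tibble (from [detect_peaks()] or
#'   [nearest_peak()]).
#' @param params [quantify_params()].
#' @param seg_start,seg_end Segment bounds (samples) isolating this event
#'   from its neighbours.
#' @param local_baseline Event-local baseline level (0 for properly
#'   baselined traces).
#' @param noise_sd Optional pre-computed baseline noise SD for SNR.
#' @param roi ROI id carried through.
#' @return One-row event tibble (see [write_event_table()] for columns).
#' @export
quantify_event <- function(values, time, peak, params = quantify_params(),
                           seg_start = 1L, seg_end = length(values),
                           local_baseline = 0, noise_sd = NA_real_,
                           roi = NA_character_) {
  ip <- peak$index
  ys <- if (params$smooth) smooth_trace(values, n = params$sg_n) else values
  amp <- ys[ip] - local_baseline
  io <- find_onset(ys, ip, params$onset_fraction, local_baseline, seg_start)
  flags <- character(0)
  if (is.na(io)) flags <- c(flags, "onset_undefined")
  dec <- fit_decay(values - local_baseline, time, ip, seg_end, ys - local_baseline,
                   params$decay_return_fraction)
  if (dec$flag != "ok") flags <- c(flags, paste0("decay_", dec$flag))
  ris <- if (is.na(io)) {
    list(tau_rise_s = NA_real_, r2 = NA_real_, flag = "rise_unfittable")
  } else {
    fit_rise(values - local_baseline, time, io, ip, dec$tau_decay_s, seg_end)
  }
  if (ris$flag != "ok") flags <- c(flags, paste0("rise_", ris$flag))
  # integration window: onset (or peak) to first return below the return
  # fraction, capped at the segment end
  int0 <- if (is.na(io)) ip else io
  j <- which(ys[ip:seg_end] - local_baseline < params$decay_return_fraction * amp)[1]
  int1 <- if (is.na(j)) seg_end else ip + j - 1L
  w <- int0:int1
  sum_df <- if (length(w) > 1) {
    sum(diff(time[w]) * (head(values[w] - local_baseline, -1) +
                           tail(values[w] - local_baseline, -1)) / 2)
  } else 0
  snr <- if (is.finite(noise_sd) && noise_sd > 0) amp / noise_sd else NA_real_
  tibble(
    roi = roi,
    peak_index = as.integer(ip),
    peak_time_s = time[ip],
    amplitude = amp,
    onset_time_s = if (is.na(io)) NA_real_ else time[io],
    tau_rise_s = ris$tau_rise_s,
    tau_decay_s = dec$tau_decay_s,
    sum_df = sum_df,
    fit_amplitude = dec$y_peak_fit,
    fit_r2_rise = ris$r2,
    fit_r2_decay = dec$r2,
    snr = snr,
    provenance = peak$provenance %||% "auto",
    flags = if (length(flags)) paste(flags, collapse = ";") else "ok"
  )
}

#' Quantify all detected events of a trace
#'
#' Segments the trace at the detected peaks (each event's fit and
#' integration windows are capped at its neighbours), estimates the
#' baseline noise SD from the event-free samples, and quantifies every
#' event. Detected events are never dropped: unfittable kinetics yield
#' `NA` constants plus a flag.
#'
#' @param norm A `norm_trace` (or numeric vector with `time`).
#' @param peaks Peak tibble from [detect_peaks()] / [edit_events()].
#' @param params [quantify_params()].
#' @param time Seconds (when `norm` is a bare vector).
#' @param roi ROI id carried through.
#' @return Event tibble, one row per peak.
#' @export
quantify_events <- function(norm, peaks, params = quantify_params(),
                            time = NULL, roi = NA_character_) {
  if (inherits(norm, "norm_trace")) {
    time <- time %||% norm$time_s
    values <- norm$value
    if (!is.na(attr(norm, "roi") %||% NA) && is.na(roi)) roi <- attr(norm, "roi")
  } else {
    values <- norm
    if (is.null(time)) time <- seq_along(values) - 1
  }
  if (!nrow(peaks)) {
    empty <- tibble(index = 1L, provenance = "auto")
    return(quantify_event(values, time, empty, params)[0, ])
  }
  n <- length(values)
  dt <- median(diff(time))
  idx <- peaks$index
  # event-free mask for the noise estimate: exclude a generous window
  # around every peak
  masked <- rep(FALSE, n)
  pad_pre <- as.integer(ceiling(0.15 / dt))
  pad_post <- as.integer(ceiling(0.6 / dt))
  for (ip in idx) {
    masked[max(1, ip - pad_pre):min(n, ip + pad_post)] <- TRUE
  }
  noise_sd <- if (any(!masked)) sd(values[!masked]) else NA_real_
  purrr::map_dfr(seq_along(idx), function(k) {
    seg_start <- if (k == 1) 1L else idx[k - 1] + 1L
    seg_end <- if (k == length(idx)) n else idx[k + 1] - 1L
    quantify_event(values, time, peaks[k, ], params,
                   seg_start = seg_start, seg_end = seg_end,
                   noise_sd = noise_sd, roi = roi)
  })
}
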