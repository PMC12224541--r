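#' Spontaneous (mini) event analysis pipeline
#'
#' Normalize -> detect -> quantify for every ROI of a trace set, without
#' stimulus partitioning. The mini frequency is `n_events / duration`.
#'
#' @param trace A [trace_set()].
#' @param params [detection_params()].
#' @param baseline [baseline_spec()]; default rolling 10th percentile,
#'   2 s window (suits drifting spontaneous recordings).
#' @param mode `"dff"` or `"drr"` (default follows the channels present).
#' @param qparams [quantify_params()].
#' @param refine_baseline Re-reference the trace to the event-masked
#'   rolling-mean baseline after the first detection pass (see
#'   [rebaseline_eventfree()]), then re-detect. Default `TRUE`; the
#'   low-percentile first-pass baseline alone is biased below the true
#'   baseline on noisy traces.
#' @return List: `events` (tibble over all ROIs), `summary` (per-ROI
#'   tibble: `n_events`, `frequency_hz`, `mean_amplitude`,
#'   `median_tau_decay_s`), `norm` (the normalized long tibble).
#' @export
run_mini <- function(trace, params,
                     baseline = baseline_spec("rolling_percentile"),
                     mode = NULL, qparams = quantify_params(),
                     refine_baseline = TRUE) {
  norm <- normalize_traces(trace, mode = mode, spec = baseline)
  dur <- max(norm$time_s)
  events <- purrr::map_dfr(trace_rois(trace), function(r) {
    d <- norm[norm$roi == r, ]
    v <- d$value
    vs <- if (qparams$smooth) smooth_trace(v, n = qparams$sg_n) else v
    pk <- detect_peaks(vs, d$time_s, params)
    if (refine_baseline) {
      v <- rebaseline_eventfree(v, d$time_s, pk)
      norm$value[norm$roi == r] <<- v
      vs <- if (qparams$smooth) smooth_trace(v, n = qparams$sg_n) else v
      pk <- detect_peaks(vs, d$time_s, params)
    }
    quantify_events(v, pk, qparams, time = d$time_s, roi = r)
  })
  summary <- if (nrow(events)) {
    events |>
      group_by(.data$roi) |>
      summarise(
        n_events = n(),
        frequency_hz = n() / dur,
        mean_amplitude = mean(.data$amplitude),
        median_tau_decay_s = median(.data$tau_decay_s, na.rm = TRUE),
        .groups = "drop"
      )
  } else {
    tibble(roi = trace_rois(trace), n_events = 0L, frequency_hz = 0,
           mean_amplitude = NA_real_, median_tau_decay_s = NA_real_)
  }
  list(events = events, summary = summary, norm = norm)
}

#' Evoked event analysis pipeline
#'
#' Normalize (pre-stimulus baseline) -> detect -> quantify -> partition by
#' the stimulation protocol.
#'
#' @inheritParams run_mini
#' @param protocol A [stim_protocol()].
#' @param response_window_s Passed to [partition_evoked()].
#' @return List: `events`, `assignments` (named per ROI), `summary`
#'   (per-ROI glance rows), `norm`.
#' @export
run_evoked <- function(trace, protocol, params,
                       baseline = baseline_spec("prestimulus_mean"),
                       mode = NULL, qparams = quantify_params(),
                       response_window_s = NULL) {
  if (is.null(protocol)) stop_synca("evoked analysis needs a protocol", "config_error")
  norm <- normalize_traces(trace, mode = mode, spec = baseline)
  assignments <- list()
  events <- purrr::map_dfr(trace_rois(trace), function(r) {
    d <- norm[norm$roi == r, ]
    vs <- if (qparams$smooth) smooth_trace(d$value, n = qparams$sg_n) else d$value
    pk <- detect_peaks(vs, d$time_s, params)
    quantify_events(d$value, pk, qparams, time = d$time_s, roi = r)
  })
  summary <- purrr::map_dfr(trace_rois(trace), function(r) {
    asg <- partition_evoked(events[events$roi == r, ], protocol, response_window_s)
    assignments[[r]] <<- asg
    mutate(glance(asg), roi = r, .before = 1)
  })
  list(events = events, assignments = assignments, summary = summary, norm = norm)
}

#' Optical-vs-electrophysiology matching pipeline
#'
#' Runs the mini pipeline on the optical trace, then matches the detected
#' optical events against the mEPSP list.
#'
#' @inheritParams run_mini
#' @param ephys An [ephys_events()] tibble.
#' @param tolerance_s Matching tolerance in seconds.
#' @return List: `match` (a `match_result`), `events`, `summary`
#'   (glance row). Warns when the median |lag| exceeds half the tolerance
#'   (possible clock misalignment).
#' @export
run_match <- function(trace, ephys, params, tolerance_s = 0.1,
                      baseline = baseline_spec("rolling_percentile"),
                      mode = NULL, qparams = quantify_params()) {
  mini <- run_mini(trace, params, baseline, mode, qparams)
  res <- match_events(mini$events, ephys, tolerance_s)
  if (res$n_pairs > 0 && median(abs(res$pairs$lag_s)) > tolerance_s / 2) {
    warn("median |lag| exceeds half the tolerance: check clock alignment (t0 offset)")
  }
  list(match = res, events = mini$events, summary = glance(res))
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records every parameter plus seed and package version as JSON,
#' sufficient to reproduce the run exactly.
#'
#' @param path Output JSON path.
#' @param config Named list of run parameters.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config) {
  config$package_version <- as.character(utils::packageVersion("synca"))
  config$r_version <- R.version.string
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(path)
}
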