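#' Describe a stimulation protocol
#'
#' Either give explicit stimulus times, or a train descriptor:
#' `frequency_hz` pulses grouped as `pulses_per_burst` per burst, bursts
#' repeating every `burst_period_s`, starting at `start_s`. A continuous
#' protocol (e.g. 1 Hz for 15 s) is a descriptor with
#' `pulses_per_burst = 1` and `burst_period_s = 1 / frequency_hz`, or
#' simply `n_bursts` single-pulse bursts.
#'
#' @param times_s Explicit stimulus times (seconds, strictly increasing);
#'   overrides the descriptor.
#' @param frequency_hz Within-burst pulse frequency.
#' @param pulses_per_burst Pulses per burst (default 1).
#' @param burst_period_s Burst repetition period in seconds (default
#'   `pulses_per_burst / frequency_hz`, i.e. contiguous).
#' @param n_bursts Number of bursts.
#' @param start_s Time of the first pulse.
#' @return A `stim_protocol` with `$times_s` and the descriptor fields.
#' @examples
#' # 1 Hz for 15 s starting at 0.5 s: 15 stimuli
#' stim_protocol(frequency_hz = 1, n_bursts = 15, start_s = 0.5)
#' # five pulses per 2-second burst at 10 Hz
#' stim_protocol(frequency_hz = 10, pulses_per_burst = 5,
#'               burst_period_s = 2, n_bursts = 2)
#' @export
stim_protocol <- function(times_s = NULL, frequency_hz = NULL,
                          pulses_per_burst = 1, burst_period_s = NULL,
                          n_bursts = NULL, start_s = 0) {
  if (!is.null(times_s)) {
    if (anyNA(times_s)) stop_synca("stimulus times contain NA", "protocol_error")
    if (is.unsorted(times_s, strictly = TRUE)) {
      stop_synca("stimulus times must be strictly increasing", "protocol_error")
    }
    return(structure(list(times_s = as.numeric(times_s), descriptor = "explicit",
                          pulses_per_burst = 1L, n_bursts = length(times_s)),
                     class = "stim_protocol"))
  }
  if (is.null(frequency_hz) || is.null(n_bursts)) {
    stop_synca("need explicit times or (frequency_hz, n_bursts)", "protocol_error")
  }
  burst_period_s <- burst_period_s %||% (pulses_per_burst / frequency_hz)
  if (pulses_per_burst / frequency_hz > burst_period_s + 1e-12) {
    stop_synca("bursts overlap: pulses_per_burst / frequency_hz exceeds burst_period_s",
               "protocol_error")
  }
  times <- as.vector(vapply(seq_len(n_bursts) - 1, function(b) {
    start_s + b * burst_period_s + (seq_len(pulses_per_burst) - 1) / frequency_hz
  }, numeric(pulses_per_burst)))
  structure(
    list(times_s = times, descriptor = "train", frequency_hz = frequency_hz,
         pulses_per_burst = as.integer(pulses_per_burst),
         burst_period_s = burst_period_s, n_bursts = as.integer(n_bursts),
         start_s = start_s),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d stimuli (%s)\n", length(x$times_s), x$descriptor))
  invisible(x)
}

#' @export
tidy.stim_protocol <- function(x, ...) {
  ppb <- x$pulses_per_burst
  k <- seq_along(x$times_s)
  tibble(
    stimulus = k, time_s = x$times_s,
    burst = ((k - 1) %/% ppb) + 1L,
    position = ((k - 1) %% ppb) + 1L
  )
}

#' Partition detected events among stimuli
#'
#' Each stimulus claims the earliest unassigned event whose peak time lies
#' in `(stimulus_time, stimulus_time + response_window_s]` (causal,
#' one-to-one). Unclaimed stimuli are failures. The response window
#' defaults to `min(inter-stimulus interval, 0.5 s)` and is clipped, with
#' a warning, when it exceeds the shortest inter-stimulus interval.
#'
#' @param events Event tibble (sorted by `peak_time_s`), e.g. from
#'   [quantify_events()].
#' @param protocol A [stim_protocol()].
#' @param response_window_s Response window in seconds, or `NULL` for the
#'   default.
#' @return An `evoked_assignment`: tibble with one row per stimulus
#'   (`stimulus`, `stimulus_time_s`, `burst`, `position`, `event_peak_time_s`,
#'   `amplitude`, `failure`), attributes `failure_rate`,
#'   `response_window_s`, `protocol`. `amplitude` is 0 for failures;
#'   `per-stimulus` rows keep event columns `NA` on failure.
#' @export
partition_evoked <- function(events, protocol, response_window_s = NULL) {
  st <- protocol$times_s
  isi <- if (length(st) > 1) min(diff(st)) else Inf
  win <- response_window_s %||% min(isi, 0.5)
  if (win > isi) {
    warn(sprintf("response window %.3g s exceeds the %.3g s inter-stimulus interval; clipped",
                 win, isi))
    win <- isi
  }
  ev_t <- events$peak_time_s
  ev_amp <- events$amplitude
  taken <- rep(FALSE, length(ev_t))
  rows <- purrr::map_dfr(seq_along(st), function(k) {
    ok <- which(!taken & ev_t > st[k] & ev_t <= st[k] + win)
    if (length(ok)) {
      i <- ok[1]
      taken[i] <<- TRUE
      tibble(stimulus = k, stimulus_time_s = st[k], event_index = i,
             event_peak_time_s = ev_t[i], amplitude = ev_amp[i], failure = FALSE)
    } else {
      tibble(stimulus = k, stimulus_time_s = st[k], event_index = NA_integer_,
             event_peak_time_s = NA_real_, amplitude = 0, failure = TRUE)
    }
  })
  ppb <- protocol$pulses_per_burst %||% 1L
  rows$burst <- ((rows$stimulus - 1) %/% ppb) + 1L
  rows$position <- ((rows$stimulus - 1) %% ppb) + 1L
  structure(rows,
    class = c("evoked_assignment", class(tibble())),
    failure_rate = mean(rows$failure),
    response_window_s = win,
    n_unassigned_events = sum(!taken),
    protocol = protocol
  )
}

#' @export
glance.evoked_assignment <- function(x, ...) {
  tibble(
    n_stimuli = nrow(x),
    n_responses = sum(!x$failure),
    n_failures = sum(x$failure),
    failure_rate = attr(x, "failure_rate"),
    response_window_s = attr(x, "response_window_s"),
    mean_amplitude = mean(x$amplitude[!x$failure])
  )
}

#' Measure per-stimulus train amplitudes from a trace
#'
#' For burst stimulation, later responses ride on the decaying tails of
#' earlier ones. Amplitudes here are segment-relative: for each stimulus
#' the response is the maximum of the (smoothed) trace in the response
#' window minus the trace value at the last sample at or before the
#' stimulus, making per-position amplitudes comparable across the burst.
#'
#' @param norm A `norm_trace` (or numeric vector plus `time`).
#' @param protocol A [stim_protocol()].
#' @param response_window_s Window after each stimulus; default
#'   `min(ISI, 0.5)`.
#' @param smooth Smooth before measuring (default `TRUE`).
#' @param time Seconds when `norm` is a bare vector.
#' @return Tibble: `stimulus`, `burst`, `position`, `stimulus_time_s`,
#'   `peak_time_s`, `amplitude` (segment-relative), `raw_peak` (absolute
#'   trace value at the in-window maximum).
#' @export
train_amplitudes <- function(norm, protocol, response_window_s = NULL,
                             smooth = TRUE, time = NULL) {
  if (inherits(norm, "norm_trace")) {
    time <- time %||% norm$time_s
    values <- norm$value
  } else {
    values <- norm
    if (is.null(time)) time <- seq_along(values) - 1
  }
  ys <- if (smooth) smooth_trace(values) else values
  st <- protocol$times_s
  isi <- if (length(st) > 1) min(diff(st)) else Inf
  win <- response_window_s %||% min(isi, 0.5)
  ppb <- protocol$pulses_per_burst %||% 1L
  purrr::map_dfr(seq_along(st), function(k) {
    pre_i <- max(which(time <= st[k]))
    w <- which(time > st[k] & time <= st[k] + win)
    if (!length(w)) {
      return(tibble(stimulus = k, burst = ((k - 1) %/% ppb) + 1L,
                    position = ((k - 1) %% ppb) + 1L, stimulus_time_s = st[k],
                    peak_time_s = NA_real_, amplitude = NA_real_, raw_peak = NA_real_))
    }
    im <- w[which.max(ys[w])]
    tibble(stimulus = k, burst = ((k - 1) %/% ppb) + 1L,
           position = ((k - 1) %% ppb) + 1L, stimulus_time_s = st[k],
           peak_time_s = time[im], amplitude = ys[im] - ys[pre_i],
           raw_peak = ys[im])
  })
}

#' Summarise a stimulation train across bursts
#'
#' Per-position mean amplitude and the facilitation index (position k
#' mean divided by position 1 mean). Positions where every burst failed
#' are reported `NA`, not 0.
#'
#' @param assignment An `evoked_assignment` (or any tibble with
#'   `position`, `amplitude` and logical `failure` columns; rows from
#'   [train_amplitudes()] work with `failure` absent).
#' @return Tibble: `position`, `n_responses`, `mean_amplitude`,
#'   `facilitation_index`.
#' @export
train_summary <- function(assignment) {
  x <- as_tibble(assignment)
  if (!nrow(x)) stop_synca("no bursts to summarise", "parameter_error")
  if (!"failure" %in% names(x)) x$failure <- is.na(x$amplitude)
  s <- x |>
    group_by(.data$position) |>
    summarise(
      n_responses = sum(!.data$failure),
      mean_amplitude = if (any(!.data$failure)) {
        mean(.data$amplitude[!.data$failure])
      } else NA_real_,
      .groups = "drop"
    )
  ref <- s$mean_amplitude[s$position == 1]
  s$facilitation_index <- if (length(ref) && is.finite(ref) && ref != 0) {
    s$mean_amplitude / ref
  } else NA_real_
  s
}
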