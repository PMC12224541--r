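#' Event kernel parameters
#'
#' @param tau_rise_s,tau_decay_s Rise and decay time constants in seconds,
#'   > 0. A rise slower than the decay is allowed but warned about.
#' @param amplitude_mean Mean event amplitude in normalized (dF/F or dR/R)
#'   units.
#' @param amplitude_cv Coefficient of variation of event amplitudes
#'   (lognormal, parameterized so the *median* equals `amplitude_mean`;
#'   0 = fixed amplitude).
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(tau_rise_s, tau_decay_s, amplitude_mean,
                          amplitude_cv = 0) {
  if (tau_rise_s <= 0 || tau_decay_s <= 0 || amplitude_mean <= 0 || amplitude_cv < 0) {
    stop_synca("kernel parameters must be positive", "parameter_error")
  }
  if (tau_rise_s >= tau_decay_s) {
    warn("tau_rise_s >= tau_decay_s: unusual kernel shape")
  }
  structure(list(tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
                 amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv),
            class = "kernel_params")
}

#' Analytic peak time of the rise-decay kernel
#'
#' The kernel `k(t) = (1 - exp(-t/tau_r)) * exp(-t/tau_d)` peaks at
#' `t* = tau_r * log(1 + tau_d / tau_r)`.
#'
#' @param kernel A [kernel_params()].
#' @return Peak time in seconds.
#' @export
kernel_peak_time <- function(kernel) {
  kernel$tau_rise_s * log(1 + kernel$tau_decay_s / kernel$tau_rise_s)
}

kernel_peak_value <- function(kernel) {
  ts <- kernel_peak_time(kernel)
  (1 - exp(-ts / kernel$tau_rise_s)) * exp(-ts / kernel$tau_decay_s)
}

#' Sample the unit-peak event kernel
#'
#' `k(t) = (1 - exp(-t/tau_r)) * exp(-t/tau_d)`, normalized by its
#' analytic maximum so the continuous-time peak is exactly 1, sampled at
#' `fps` and truncated once the tail falls below `1e-4` (support is also
#' capped at 60 s for near-non-decaying kernels).
#'
#' @param kernel A [kernel_params()].
#' @param fps Sampling rate, frames per second.
#' @return Numeric vector, `k[1]` at t = 0.
#' @export
event_kernel <- function(kernel, fps) {
  tr <- kernel$tau_rise_s; td <- kernel$tau_decay_s
  pk <- kernel_peak_value(kernel)
  ts <- kernel_peak_time(kernel)
  # tail truncation point: after the peak, k = 1e-4 at
  # t ~ td * log(1e4) past the peak (rise factor ~ 1)
  t_end <- min(ts + td * log(1 / (1e-4 * pk)) + 5 / fps, 60)
  t <- seq(0, t_end, by = 1 / fps)
  k <- (1 - exp(-t / tr)) * exp(-t / td) / pk
  last <- max(which(k >= 1e-4))
  k[seq_len(last)]
}

#' Simulation configuration
#'
#' Describes a synthetic two-channel bouton recording: baseline
#' fluorescence with events of known kinetics, optional photobleaching,
#' shared multiplicative gain fluctuation between channels, and additive
#' Gaussian noise per channel.
#'
#' @param fps Frame rate (frames/s).
#' @param duration_s Recording length (s).
#' @param kernel A [kernel_params()].
#' @param event_model `"poisson"` (rate `rate_hz`) or `"protocol"`
#'   (stimulus-driven: `protocol`, `latency_mean_s`, `latency_jitter_s`,
#'   `failure_p`).
#' @param rate_hz Poisson event rate.
#' @param protocol A [stim_protocol()] for the protocol model.
#' @param latency_mean_s,latency_jitter_s,failure_p Stimulus-to-event
#'   latency (mean, Gaussian jitter SD) and release-failure probability.
#' @param baseline_f Baseline fluorescence of the signal channel
#'   (arbitrary units).
#' @param bleach_tau_s Photobleaching time constant (s), or `NULL`.
#' @param shared_gain_cv CV of the per-frame multiplicative gain shared by
#'   both channels (lognormal, mean 1; 0 disables).
#' @param noise_sd Additive Gaussian noise SD on the signal channel
#'   (fluorescence units).
#' @param reference_level Baseline of the Ca2+-insensitive reference
#'   channel; `NULL` for single-channel simulation.
#' @param reference_noise_sd Additive noise SD on the reference channel.
#' @param seed Integer seed fixing all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(fps = 115, duration_s = 60, kernel,
                       event_model = c("poisson", "protocol"), rate_hz = 2,
                       protocol = NULL, latency_mean_s = 0.01,
                       latency_jitter_s = 0.002, failure_p = 0,
                       baseline_f = 100, bleach_tau_s = NULL,
                       shared_gain_cv = 0, noise_sd = 0,
                       reference_level = NULL, reference_noise_sd = 0,
                       seed = 1L) {
  event_model <- match.arg(event_model)
  if (fps <= 0 || duration_s <= 0 || noise_sd < 0 || shared_gain_cv < 0) {
    stop_synca("invalid simulation parameters", "parameter_error")
  }
  if (event_model == "protocol" && is.null(protocol)) {
    stop_synca("protocol event model needs a stim_protocol", "parameter_error")
  }
  structure(
    list(fps = fps, duration_s = duration_s, kernel = kernel,
         event_model = event_model, rate_hz = rate_hz, protocol = protocol,
         latency_mean_s = latency_mean_s, latency_jitter_s = latency_jitter_s,
         failure_p = failure_p, baseline_f = baseline_f,
         bleach_tau_s = bleach_tau_s, shared_gain_cv = shared_gain_cv,
         noise_sd = noise_sd, reference_level = reference_level,
         reference_noise_sd = reference_noise_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

draw_events <- function(cfg) {
  if (cfg$event_model == "poisson") {
    n <- rpois(1, cfg$rate_hz * cfg$duration_s)
    times <- sort(runif(n, 0, cfg$duration_s))
  } else {
    st <- cfg$protocol$times_s
    keep <- runif(length(st)) >= cfg$failure_p
    times <- st[keep] + cfg$latency_mean_s +
      if (cfg$latency_jitter_s > 0) rnorm(sum(keep), 0, cfg$latency_jitter_s) else 0
    times <- sort(times[times >= 0 & times < cfg$duration_s])
  }
  k <- cfg$kernel
  amps <- if (k$amplitude_cv > 0) {
    sdlog <- sqrt(log(1 + k$amplitude_cv^2))
    rlnorm(length(times), meanlog = log(k$amplitude_mean), sdlog = sdlog)
  } else {
    rep(k$amplitude_mean, length(times))
  }
  tibble(time_s = times, amplitude = amps)
}

#' Simulate a two-channel trace set with ground truth
#'
#' Signal channel:
#' `F_i = gain_i * bleach_i * baseline_f * (1 + sum_e a_e k(t_i - t_e)) + noise_i`;
#' reference channel:
#' `R_i = gain_i * bleach_i * reference_level + ref_noise_i`,
#' with the same lognormal gain series in both channels. Event
#' superposition is linear; the same seed gives bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @param roi ROI id for the emitted trace.
#' @return List: `traces` (a [trace_set()]) and `truth` (list with
#'   `events` tibble, `kernel`, `gain`, `config`).
#' @export
simulate_traces <- function(cfg, roi = "roi1") {
  withr::with_seed(cfg$seed, {
    dt <- 1 / cfg$fps
    nf <- as.integer(floor(cfg$duration_s / dt)) + 1L
    t <- (seq_len(nf) - 1) * dt
    events <- draw_events(cfg)
    ker_len <- length(event_kernel(cfg$kernel, cfg$fps))
    pkv <- kernel_peak_value(cfg$kernel)
    resp <- numeric(nf)
    for (e in seq_len(nrow(events))) {
      # kernel evaluated analytically at the exact offsets of the frame
      # grid from the (continuous) event time
      i0 <- as.integer(ceiling(events$time_s[e] / dt)) + 1L
      if (i0 > nf) next
      i1 <- min(nf, i0 + ker_len)
      tk <- t[i0:i1] - events$time_s[e]
      kk <- (1 - exp(-tk / cfg$kernel$tau_rise_s)) *
        exp(-tk / cfg$kernel$tau_decay_s) / pkv
      resp[i0:i1] <- resp[i0:i1] + events$amplitude[e] * kk
    }
    if (nrow(events) > 1) {
      overlap <- mean(resp > 0.01 * max(events$amplitude))
      if (overlap > 0.9) warn("event rate so high that kernels overlap >90% of frames")
    }
    gain <- if (cfg$shared_gain_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$shared_gain_cv^2))
      rlnorm(nf, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, nf)
    }
    bleach <- if (!is.null(cfg$bleach_tau_s)) exp(-t / cfg$bleach_tau_s) else rep(1, nf)
    f <- gain * bleach * cfg$baseline_f * (1 + resp) +
      if (cfg$noise_sd > 0) rnorm(nf, 0, cfg$noise_sd) else 0
    d <- tibble(roi = roi, frame = seq_len(nf) - 1L, signal = f)
    if (!is.null(cfg$reference_level)) {
      d$reference <- gain * bleach * cfg$reference_level +
        if (cfg$reference_noise_sd > 0) rnorm(nf, 0, cfg$reference_noise_sd) else 0
    }
    traces <- trace_set(d, frame_interval_s = dt,
                        meta = list(fps = cfg$fps, simulated = TRUE))
    list(traces = traces,
         truth = list(events = events, kernel = cfg$kernel, gain = gain,
                      config = cfg))
  })
}

#' Simulate paired optical + electrophysiological recordings
#'
#' One mEPSP per true event (amplitude = truth amplitude * `mv_scale` +
#' Gaussian noise); the optical trace independently omits each event with
#' probability `miss_p` (a sensor-sensitivity miss process). Ground truth
#' records which events were omitted.
#'
#' @param cfg A [sim_config()].
#' @param miss_p Per-event optical miss probability in [0, 1).
#' @param mv_scale mV per unit of normalized optical amplitude.
#' @param mv_noise_sd Gaussian SD of the mEPSP amplitude noise (mV).
#' @return List: `traces`, `ephys` (an [ephys_events()] tibble), `truth`
#'   (events tibble with `optical_present` flag).
#' @export
simulate_paired <- function(cfg, miss_p = 0, mv_scale = 1, mv_noise_sd = 0) {
  if (miss_p < 0 || miss_p >= 1) stop_synca("`miss_p` must be in [0, 1)", "parameter_error")
  withr::with_seed(cfg$seed, {
    events <- draw_events(cfg)
    present <- runif(nrow(events)) >= miss_p
    mv <- events$amplitude * mv_scale +
      if (mv_noise_sd > 0) rnorm(nrow(events), 0, mv_noise_sd) else 0
    mv <- pmax(mv, 1e-6)
    seed2 <- cfg$seed + 1000003L
  })
  opt_cfg <- cfg
  opt_cfg$seed <- seed2
  # re-inject the surviving events as an explicit protocol with no jitter
  opt_cfg$event_model <- "protocol"
  opt_cfg$protocol <- stim_protocol(times_s = events$time_s[present])
  opt_cfg$latency_mean_s <- 0
  opt_cfg$latency_jitter_s <- 0
  opt_cfg$failure_p <- 0
  amp_saved <- opt_cfg$kernel$amplitude_cv
  opt_cfg$kernel$amplitude_cv <- 0
  sim <- simulate_traces(opt_cfg)
  # restore the true per-event amplitudes (draw_events with cv 0 gives the
  # mean for every event; rebuild the response with the correct amplitudes)
  if (amp_saved > 0 || any(events$amplitude != cfg$kernel$amplitude_mean)) {
    sim <- rebuild_with_amplitudes(opt_cfg, events[present, ], cfg)
  }
  truth <- events
  truth$optical_present <- present
  truth$mv <- mv
  list(
    traces = sim$traces,
    ephys = ephys_events(events$time_s, mv, recording_duration_s = cfg$duration_s),
    truth = list(events = truth, kernel = cfg$kernel, config = cfg,
                 miss_p = miss_p)
  )
}

# deterministic rebuild used when per-event amplitudes vary
rebuild_with_amplitudes <- function(opt_cfg, events, orig_cfg) {
  cfg <- opt_cfg
  cfg$protocol <- NULL
  cfg$event_model <- "poisson"
  cfg$rate_hz <- 0
  base <- simulate_traces(cfg)  # event-free trace with same noise/gain draws
  dt <- 1 / cfg$fps
  nf <- n_frames(base$traces)
  resp <- numeric(nf)
  pkv <- kernel_peak_value(cfg$kernel)
  for (e in seq_len(nrow(events))) {
    i0 <- as.integer(floor(events$time_s[e] / dt)) + 1L
    frac <- events$time_s[e] / dt - (i0 - 1L)
    tk <- (seq_len(nf) - 1) * dt - events$time_s[e]
    kk <- ifelse(tk < 0, 0,
                 (1 - exp(-tk / cfg$kernel$tau_rise_s)) *
                   exp(-tk / cfg$kernel$tau_decay_s) / pkv)
    resp <- resp + events$amplitude[e] * kk
  }
  d <- as_tibble(base$traces)
  gain_bleach <- base$truth$gain *
    if (!is.null(cfg$bleach_tau_s)) exp(-d$time_s[d$roi == d$roi[1]] / cfg$bleach_tau_s) else 1
  d$signal <- d$signal + gain_bleach * cfg$baseline_f * resp
  traces <- trace_set(d[, setdiff(names(d), "time_s")], frame_interval_s = dt,
                      meta = list(fps = cfg$fps, simulated = TRUE))
  list(traces = traces,
       truth = list(events = events, kernel = cfg$kernel, gain = base$truth$gain,
                    config = cfg))
}

scenario_table <- list(
  synap6f = list(kernel = c(0.021, 0.099, 0.27), fps = 115, two_channel = FALSE,
                 detection_miss_p = 0.43,
                 note = "postsynaptic GCaMP6f quantal sensor"),
  synap8f = list(kernel = c(0.014, 0.042, 0.35), fps = 115, two_channel = FALSE,
                 detection_miss_p = 0.12,
                 note = "postsynaptic GCaMP8f quantal sensor"),
  synap8m = list(kernel = c(0.014, 0.067, 0.58), fps = 115, two_channel = FALSE,
                 detection_miss_p = 0.07,
                 note = "postsynaptic GCaMP8m quantal sensor"),
  scar8f = list(kernel = c(0.0053, 0.0666, 0.40), fps = 115, two_channel = TRUE,
                note = "presynaptic ratiometric GCaMP8f (single-AP dR/R); amplitude is a representative value, not a published one"),
  scar8m = list(kernel = c(0.0070, 0.0992, 0.63), fps = 115, two_channel = TRUE,
                note = "presynaptic ratiometric GCaMP8m (single-AP dR/R)"),
  wt = list(kernel = c(0.014, 0.067, 0.58), fps = 100, two_channel = FALSE,
            mepsp_mean_mv = 0.64, note = "wild-type quantal events"),
  GluRIIA = list(kernel = c(0.014, 0.067, 0.58), fps = 100, two_channel = FALSE,
                 mepsp_mean_mv = 0.38, note = "GluRIIA mutant: diminished quantal size"),
  GluRIIB = list(kernel = c(0.014, 0.067, 0.58), fps = 100, two_channel = FALSE,
                 mepsp_mean_mv = 0.82, note = "GluRIIB mutant: enlarged quantal size")
)

#' Preset simulation scenarios
#'
#' Named sensor/genotype presets whose kernel kinetics, amplitudes and
#' quantal statistics are the published single-event values for each
#' indicator (postsynaptic quantal sensors at 115 fps; presynaptic
#' ratiometric single-AP sensors; genotype presets carry mean mEPSP
#' amplitudes in mV). Event amplitudes are fixed at the preset mean
#' (`amplitude_cv = 0`) so round-trip recovery targets a single known
#' value; set a CV on the returned config for variable quantal sizes.
#'
#' @param name One of `r paste0('"', names(scenario_table), '"', collapse = ", ")`.
#' @param ... Overrides passed to [sim_config()] (e.g. `duration_s`,
#'   `noise_sd`, `seed`).
#' @return A [sim_config()] with extra fields `scenario`,
#'   `detection_miss_p` / `mepsp_mean_mv` where applicable, and `note`.
#' @export
scenario <- function(name, ...) {
  if (!name %in% names(scenario_table)) {
    stop_synca(paste0("unknown scenario '", name, "'; available: ",
                      paste(names(scenario_table), collapse = ", ")),
               "parameter_error")
  }
  s <- scenario_table[[name]]
  k <- kernel_params(s$kernel[1], s$kernel[2], s$kernel[3], amplitude_cv = 0)
  args <- list(...)
  noise_default <- s$kernel[3] / 10  # noise SD = amplitude / 10, in dF/F units
  base <- list(
    fps = s$fps, duration_s = 60, kernel = k, event_model = "poisson",
    rate_hz = 0.5, baseline_f = 100,
    noise_sd = 100 * noise_default,
    reference_level = if (s$two_channel) 50 else NULL,
    shared_gain_cv = if (s$two_channel) 0.2 else 0
  )
  cfg <- do.call(sim_config, modifyList(base, args))
  cfg$scenario <- name
  cfg$detection_miss_p <- s$detection_miss_p %||% NA_real_
  cfg$mepsp_mean_mv <- s$mepsp_mean_mv %||% NA_real_
  cfg$note <- s$note
  cfg
}
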