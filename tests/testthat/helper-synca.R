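# Independent brute-force oracles and small generators used across the
# suite. These deliberately re-derive every quantity with plain loops,
# sharing no code with the package internals they check.

# closed-form rise*decay transient, zero before onset
oracle_kernel <- function(t, tau_r, tau_d) {
  k <- (1 - exp(-t / tau_r)) * exp(-t / tau_d)
  k[t < 0] <- 0
  k
}

oracle_kernel_peak_t <- function(tau_r, tau_d) tau_r * log(1 + tau_d / tau_r)

oracle_kernel_unit <- function(t, tau_r, tau_d) {
  ts <- oracle_kernel_peak_t(tau_r, tau_d)
  oracle_kernel(t, tau_r, tau_d) / oracle_kernel(ts, tau_r, tau_d)
}

# exhaustive local maxima: strict rise into the sample, plateau reports its
# first sample, boundaries excluded
oracle_local_maxima <- function(v) {
  n <- length(v)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (v[i] <= v[i - 1]) next
    j <- i
    while (j < n && v[j + 1] == v[j]) j <- j + 1
    if (j < n && v[j + 1] < v[j]) out <- c(out, i)
  }
  out
}

# prominence + half-prominence width by direct scan, written from the
# documented definition
oracle_prom_width <- function(v, time, ip) {
  n <- length(v)
  h <- v[ip]
  rng_l <- ip
  while (rng_l > 1 && v[rng_l - 1] <= h) rng_l <- rng_l - 1
  rng_r <- ip
  while (rng_r < n && v[rng_r + 1] <= h) rng_r <- rng_r + 1
  il <- if (rng_l < ip) (rng_l:(ip - 1))[which.min(v[rng_l:(ip - 1)])] else max(1, ip - 1)
  ir <- if (rng_r > ip) ((ip + 1):rng_r)[which.min(v[(ip + 1):rng_r])] else min(n, ip + 1)
  prom <- h - max(v[il], v[ir])
  level <- h - prom / 2
  xl <- time[il]
  for (i in seq(ip - 1, il)) {
    if (v[i] <= level) {
      xl <- if (v[i] == level || v[i + 1] == v[i]) time[i] else {
        time[i + 1] + (v[i + 1] - level) / (v[i + 1] - v[i]) * (time[i] - time[i + 1])
      }
      break
    }
  }
  xr <- time[ir]
  for (i in seq(ip + 1, ir)) {
    if (v[i] <= level) {
      xr <- if (v[i] == level || v[i - 1] == v[i]) time[i] else {
        time[i - 1] + (v[i - 1] - level) / (v[i - 1] - v[i]) * (time[i] - time[i - 1])
      }
      break
    }
  }
  c(prom = prom, width = xr - xl)
}

# full detection oracle: enumerate, threshold, width-filter, then greedy
# keep-highest distance filter (tie -> earlier)
oracle_detect <- function(v, time, threshold, min_width_s = 0, min_distance_s = 0) {
  cand <- oracle_local_maxima(v)
  cand <- cand[v[cand] >= threshold]
  if (min_width_s > 0 && length(cand)) {
    keep <- vapply(cand, function(ip) {
      oracle_prom_width(v, time, ip)[["width"]] >= min_width_s
    }, logical(1))
    cand <- cand[keep]
  }
  if (min_distance_s > 0 && length(cand) > 1) {
    ord <- cand[order(-v[cand], time[cand])]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(time[i] - time[kept]) >= min_distance_s)) {
        kept <- c(kept, i)
      }
    }
    cand <- sort(kept)
  }
  cand
}

# exhaustive one-to-one assignment (crossings allowed) maximizing pair
# count then minimizing total |lag|; returns c(n_pairs, total_lag)
oracle_assignment <- function(ta, tb, tol) {
  best <- c(0, Inf)
  recurse <- function(i, pairs, lag, used_b) {
    if (i > length(ta)) {
      if (pairs > best[1] || (pairs == best[1] && lag < best[2])) {
        best <<- c(pairs, lag)
      }
      return(invisible())
    }
    # remaining upper bound prune
    if (pairs + (length(ta) - i + 1) < best[1]) return(invisible())
    recurse(i + 1, pairs, lag, used_b)
    for (j in seq_along(tb)) {
      if (!used_b[j] && abs(ta[i] - tb[j]) <= tol) {
        used_b[j] <- TRUE
        recurse(i + 1, pairs + 1, lag + abs(ta[i] - tb[j]), used_b)
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1, 0, 0, rep(FALSE, length(tb)))
  best
}

# two-sample KS statistic: direct sup over the pooled sample points
oracle_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1)))
}

# convenience: single-ROI trace_set from a bare signal vector
make_trace <- function(signal, dt = 0.01, reference = NULL) {
  d <- data.frame(roi = "r1", frame = seq_along(signal) - 1L, signal = signal)
  if (!is.null(reference)) d$reference <- reference
  trace_set(d, frame_interval_s = dt)
}

# an isolated-event scenario simulation used by several files
sim_isolated <- function(name, n_ev = 60, spacing = 1, seed = 5, ...) {
  cfg <- scenario(
    name,
    duration_s = n_ev * spacing + 1, seed = seed,
    event_model = "protocol",
    protocol = stim_protocol(times_s = spacing * (seq_len(n_ev) - 1) + 0.5),
    latency_mean_s = 0, latency_jitter_s = 0, ...
  )
  list(cfg = cfg, sim = simulate_traces(cfg))
}
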