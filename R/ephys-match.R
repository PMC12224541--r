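#' Construct an electrophysiology event list
#'
#' mEPSP events recorded on the same (TTL-aligned) clock as the imaging.
#'
#' @param times_s Event times in seconds, sorted.
#' @param amplitudes_mv Event amplitudes in millivolts, > 0.
#' @param recording_duration_s Recording length in seconds.
#' @param t0_offset_s Clock offset added to `times_s` (TTL start
#'   correction).
#' @return Tibble with columns `time_s`, `amplitude_mv` and attribute
#'   `recording_duration_s`.
#' @export
ephys_events <- function(times_s, amplitudes_mv,
                         recording_duration_s = max(times_s), t0_offset_s = 0) {
  times_s <- times_s + t0_offset_s
  if (is.unsorted(times_s)) {
    o <- order(times_s)
    times_s <- times_s[o]
    amplitudes_mv <- amplitudes_mv[o]
  }
  if (any(amplitudes_mv <= 0)) stop_synca("mEPSP amplitudes must be > 0", "format_error")
  if (any(times_s < 0) || any(times_s > recording_duration_s)) {
    stop_synca("event times outside [0, recording_duration_s]", "format_error")
  }
  structure(tibble(time_s = times_s, amplitude_mv = amplitudes_mv),
            class = c("ephys_events", class(tibble())),
            recording_duration_s = recording_duration_s)
}

#' Read an ephys event CSV (time_s, amplitude_mV)
#'
#' @param path Two-column CSV; first column time (s), second amplitude
#'   (mV).
#' @param t0_offset_s Clock offset (s) added to the times.
#' @return An [ephys_events()] tibble.
#' @export
read_ephys_table <- function(path, t0_offset_s = 0) {
  if (!file.exists(path)) stop_synca(paste0("file not found: ", path), "io_error")
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(d) < 2) stop_synca("ephys table needs time and amplitude columns", "format_error")
  ephys_events(d[[1]], d[[2]], recording_duration_s = max(d[[1]]) + 1,
               t0_offset_s = t0_offset_s)
}

# Order-preserving (non-crossing) one-to-one matching maximizing the pair
# count and, among maximal matchings, minimizing total |lag|. Exact dynamic
# program over the two sorted lists.
dp_match <- function(ta, tb, tolerance_s) {
  n <- length(ta); m <- length(tb)
  NP <- matrix(0L, n + 1, m + 1)   # best pair count
  TL <- matrix(0, n + 1, m + 1)    # total lag at that count
  CH <- matrix(0L, n + 1, m + 1)   # 1 = skip a, 2 = skip b, 3 = match
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best_np <- NP[i, j + 1]; best_tl <- TL[i, j + 1]; ch <- 1L
      if (NP[i + 1, j] > best_np ||
          (NP[i + 1, j] == best_np && TL[i + 1, j] < best_tl)) {
        best_np <- NP[i + 1, j]; best_tl <- TL[i + 1, j]; ch <- 2L
      }
      lag <- ta[i] - tb[j]
      if (abs(lag) <= tolerance_s) {
        np <- NP[i, j] + 1L; tl <- TL[i, j] + abs(lag)
        if (np > best_np || (np == best_np && tl < best_tl)) {
          best_np <- np; best_tl <- tl; ch <- 3L
        }
      }
      NP[i + 1, j + 1] <- best_np; TL[i + 1, j + 1] <- best_tl; CH[i + 1, j + 1] <- ch
    }
  }
  pairs <- list()
  i <- n; j <- m
  while (i > 0 && j > 0) {
    ch <- CH[i + 1, j + 1]
    if (ch == 3L) {
      pairs[[length(pairs) + 1]] <- c(i, j)
      i <- i - 1; j <- j - 1
    } else if (ch == 1L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  if (!length(pairs)) {
    return(tibble(a = integer(0), b = integer(0)))
  }
  p <- do.call(rbind, rev(pairs))
  tibble(a = p[, 1], b = p[, 2])
}

#' Match optical events against electrophysiological events
#'
#' Pairs optical Ca2+ transients with mEPSPs one-to-one by an exact
#' order-preserving dynamic program that maximizes the number of pairs
#' within `tolerance_s` and, among maximal pairings, minimizes the total
#' absolute lag. The lag is measured from the optical event *onset* (the
#' physiological correlate of the electrical event; the fluorescence peak
#' lags by the rise time) to the mEPSP time; events lacking an onset fall
#' back to their peak time.
#'
#' @param optical Event tibble (needs `onset_time_s` and/or
#'   `peak_time_s`, and `amplitude`).
#' @param ephys An [ephys_events()] tibble.
#' @param tolerance_s Maximum |lag| for a pair, > 0 (default 0.1 s).
#' @return A `match_result` list: `pairs` (tibble with `ephys_index`,
#'   `optical_index`, `ephys_time_s`, `optical_time_s`, `lag_s`,
#'   `amplitude_mv`, `amplitude_optical`), `missed_ephys`,
#'   `extra_optical` (index vectors), `n_pairs`, `detection_fraction`
#'   (= n_pairs / n_ephys), `pearson_r`, `r_squared` (NA when fewer than
#'   3 pairs).
#' @export
match_events <- function(optical, ephys, tolerance_s = 0.1) {
  if (!is.numeric(tolerance_s) || tolerance_s <= 0) {
    stop_synca("`tolerance_s` must be > 0", "parameter_error")
  }
  t_opt <- optical$onset_time_s %||% optical$peak_time_s
  if (is.null(t_opt)) stop_synca("optical events need onset or peak times", "format_error")
  if (!is.null(optical$peak_time_s)) {
    t_opt <- ifelse(is.na(t_opt), optical$peak_time_s, t_opt)
  }
  o <- order(t_opt)
  t_opt_s <- t_opt[o]
  pr <- dp_match(t_opt_s, ephys$time_s, tolerance_s)
  pairs <- tibble(
    ephys_index = pr$b,
    optical_index = o[pr$a],
    ephys_time_s = ephys$time_s[pr$b],
    optical_time_s = t_opt_s[pr$a],
    lag_s = t_opt_s[pr$a] - ephys$time_s[pr$b],
    amplitude_mv = ephys$amplitude_mv[pr$b],
    amplitude_optical = optical$amplitude[o[pr$a]]
  )
  n_pairs <- nrow(pairs)
  r <- NA_real_
  if (n_pairs >= 3 && sd(pairs$amplitude_mv) > 0 && sd(pairs$amplitude_optical) > 0) {
    r <- stats::cor(pairs$amplitude_mv, pairs$amplitude_optical)
  }
  structure(
    list(
      pairs = pairs,
      missed_ephys = setdiff(seq_len(nrow(ephys)), pr$b),
      extra_optical = setdiff(seq_along(t_opt), o[pr$a]),
      n_pairs = n_pairs,
      n_ephys = nrow(ephys),
      n_optical = length(t_opt),
      detection_fraction = n_pairs / nrow(ephys),
      pearson_r = r,
      r_squared = if (is.na(r)) NA_real_ else r^2,
      tolerance_s = tolerance_s
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d/%d ephys events matched (detection fraction %.3f); r = %s\n",
    x$n_pairs, x$n_ephys, x$detection_fraction,
    if (is.na(x$pearson_r)) "NA" else sprintf("%.3f", x$pearson_r)
  ))
  invisible(x)
}

#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @export
glance.match_result <- function(x, ...) {
  tibble(
    n_ephys = x$n_ephys, n_optical = x$n_optical, n_pairs = x$n_pairs,
    n_missed_ephys = length(x$missed_ephys),
    n_extra_optical = length(x$extra_optical),
    detection_fraction = x$detection_fraction,
    pearson_r = x$pearson_r, r_squared = x$r_squared,
    tolerance_s = x$tolerance_s
  )
}

#' Pearson correlation of paired amplitudes
#'
#' @param result A `match_result` with at least 3 pairs.
#' @return Tibble: `pearson_r`, `r_squared`, `p_value`, `n`.
#' @export
amplitude_correlation <- function(result) {
  p <- result$pairs
  if (nrow(p) < 3) stop_synca("need at least 3 pairs for a correlation", "parameter_error")
  if (sd(p$amplitude_mv) == 0 || sd(p$amplitude_optical) == 0) {
    stop_synca("zero variance in one coordinate; correlation undefined", "degenerate")
  }
  ct <- cor.test(p$amplitude_mv, p$amplitude_optical)
  tibble(pearson_r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p_value = ct$p.value, n = nrow(p))
}

#' Compare two amplitude distributions (ECDFs and two-sample KS test)
#'
#' @param amplitudes_a,amplitudes_b Numeric samples, each n >= 5.
#' @return List: `ks_statistic`, `p_value`, `ecdf` (tibble with `sample`,
#'   `value`, `cumprob` for cumulative-probability plots).
#' @export
ecdf_compare <- function(amplitudes_a, amplitudes_b) {
  if (length(amplitudes_a) < 5 || length(amplitudes_b) < 5) {
    stop_synca("each sample needs at least 5 values", "insufficient_data")
  }
  ks <- suppressWarnings(ks.test(amplitudes_a, amplitudes_b))
  tab <- function(x, lab) {
    xs <- sort(x)
    tibble(sample = lab, value = xs, cumprob = seq_along(xs) / length(xs))
  }
  list(
    ks_statistic = unname(ks$statistic),
    p_value = ks$p.value,
    ecdf = bind_rows(tab(amplitudes_a, "a"), tab(amplitudes_b, "b"))
  )
}
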