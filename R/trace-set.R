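#' Construct a trace set
#'
#' A trace set holds the time base and per-ROI raw intensity traces for a
#' Ca2+-sensitive signal channel and an optional Ca2+-insensitive reference
#' channel, as exported from image-analysis software (one intensity column
#' per ROI per channel). Stored long: one row per ROI per frame.
#'
#' Frames are stamped at the start of the frame: frame `i` (0-based) occurs
#' at `i * frame_interval_s` seconds.
#'
#' @param data A data frame with columns `roi` (character), `frame`
#'   (0-based integer), `signal` (numeric intensity) and optionally
#'   `reference` (numeric intensity, strictly positive).
#' @param frame_interval_s Seconds per frame, > 0.
#' @param meta Optional named list of acquisition metadata.
#' @return A `trace_set`: a tibble with columns `roi`, `frame`, `time_s`,
#'   `signal` and (if present) `reference`, plus attributes
#'   `frame_interval_s`, `n_frames` and `meta`.
#' @examples
#' ts <- trace_set(
#'   data.frame(roi = "b1", frame = 0:9, signal = rep(100, 10)),
#'   frame_interval_s = 0.01
#' )
#' n_frames(ts)
#' @export
trace_set <- function(data, frame_interval_s, meta = list()) {
  if (!is.data.frame(data)) stop_synca("`data` must be a data frame", "type_error")
  need <- c("roi", "frame", "signal")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_synca(paste0("missing column(s): ", paste(miss, collapse = ", ")), "format_error")
  }
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1 ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0) {
    stop_synca("`frame_interval_s` must be a single positive number", "timebase_error")
  }
  d <- as_tibble(data)
  d$roi <- as.character(d$roi)
  rois <- unique(d$roi)
  nf_tbl <- table(d$roi)
  if (length(unique(as.integer(nf_tbl))) != 1) {
    bad <- names(nf_tbl)[nf_tbl != max(nf_tbl)]
    stop_synca(paste0("ragged ROI series: ", paste(bad, collapse = ", ")), "format_error")
  }
  nf <- as.integer(nf_tbl[[1]])
  if (!all(is.finite(d$signal))) stop_synca("non-finite signal intensities", "format_error")
  has_ref <- "reference" %in% names(d) && !all(is.na(d$reference))
  if (has_ref) {
    if (!all(is.finite(d$reference))) stop_synca("non-finite reference intensities", "format_error")
    if (any(d$reference <= 0)) {
      stop_synca("reference channel must be strictly positive", "reference_error")
    }
  } else {
    d$reference <- NULL
  }
  d <- d[order(match(d$roi, rois), d$frame), ]
  d$time_s <- d$frame * frame_interval_s
  cols <- c("roi", "frame", "time_s", "signal", if (has_ref) "reference")
  d <- d[, cols]
  structure(d,
    class = c("trace_set", class(tibble())),
    frame_interval_s = frame_interval_s,
    n_frames = nf,
    meta = meta
  )
}

#' @rdname trace_set
#' @param x A `trace_set`.
#' @export
frame_interval <- function(x) attr(x, "frame_interval_s")

#' @rdname trace_set
#' @export
n_frames <- function(x) attr(x, "n_frames")

#' @rdname trace_set
#' @export
trace_rois <- function(x) unique(x$roi)

#' Time base of a trace set
#'
#' Returns the vector of frame timestamps `t_i = i * frame_interval_s`,
#' i = 0 .. n_frames - 1 (start-of-frame convention).
#'
#' @param trace A `trace_set`.
#' @return Numeric vector of length `n_frames(trace)`, strictly increasing
#'   with constant step.
#' @export
timebase <- function(trace) {
  (seq_len(n_frames(trace)) - 1) * frame_interval(trace)
}

#' Extract one ROI from a trace set
#'
#' @param trace A `trace_set`.
#' @param roi ROI identifier; defaults to the first ROI.
#' @return Tibble with columns `frame`, `time_s`, `signal` and, when the
#'   trace set is two-channel, `reference`.
#' @export
trace_roi <- function(trace, roi = NULL) {
  roi <- roi %||% trace_rois(trace)[1]
  if (!roi %in% trace$roi) {
    stop_synca(paste0("unknown ROI: ", roi), "format_error")
  }
  out <- as_tibble(trace[trace$roi == roi, , drop = FALSE])
  out$roi <- NULL
  out
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf(
    "<trace_set> %d ROI(s) x %d frames @ %.6g s/frame (%s)\n",
    length(trace_rois(x)), n_frames(x), frame_interval(x),
    if ("reference" %in% names(x)) "two-channel" else "single-channel"
  ))
  NextMethod()
}
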