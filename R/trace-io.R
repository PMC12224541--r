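#' Describe the column layout of a trace table
#'
#' Imaging intensity tables have one time (or frame) column plus one column
#' per ROI per channel. The default naming convention is `<roi>_<channel>`
#' with channels `G` (Ca2+-sensitive) and `R` (reference); a bare column
#' name is treated as a single-channel ROI.
#'
#' @param time_col Name of the time column (seconds), or `NULL` when the
#'   table has no time column (then `frame_rate` is required).
#' @param frame_rate Frames per second, used when no time column exists.
#' @param channel_sep Separator between ROI id and channel suffix.
#' @param signal_suffix,reference_suffix Channel suffixes.
#' @param columns Optional explicit mapping: a data frame with columns
#'   `column`, `roi`, `channel` ("signal" or "reference") overriding the
#'   naming convention.
#' @return A `trace_schema` list.
#' @export
trace_schema <- function(time_col = "time", frame_rate = NULL,
                         channel_sep = "_", signal_suffix = "G",
                         reference_suffix = "R", columns = NULL) {
  if (is.null(time_col) && is.null(frame_rate)) {
    stop_synca("need either a time column or a frame rate", "timebase_error")
  }
  structure(
    list(
      time_col = time_col, frame_rate = frame_rate, channel_sep = channel_sep,
      signal_suffix = signal_suffix, reference_suffix = reference_suffix,
      columns = columns
    ),
    class = "trace_schema"
  )
}

read_raw_table <- function(path) {
  if (!file.exists(path)) stop_synca(paste0("file not found: ", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_synca("reading XLSX requires the readxl package", "io_error")
    }
    return(as_tibble(readxl::read_excel(path, sheet = 1)))
  }
  delim <- if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

map_columns <- function(cols, schema) {
  if (!is.null(schema$columns)) {
    m <- as_tibble(schema$columns)
    bad <- setdiff(m$column, cols)
    if (length(bad)) {
      stop_synca(paste0("schema names missing column(s): ", paste(bad, collapse = ", ")),
                 "format_error")
    }
    return(m)
  }
  sep <- schema$channel_sep
  sig_re <- paste0(sep, schema$signal_suffix, "$")
  ref_re <- paste0(sep, schema$reference_suffix, "$")
  purrr::map_dfr(cols, function(cn) {
    if (grepl(sig_re, cn)) {
      tibble(column = cn, roi = sub(sig_re, "", cn), channel = "signal")
    } else if (grepl(ref_re, cn)) {
      tibble(column = cn, roi = sub(ref_re, "", cn), channel = "reference")
    } else {
      tibble(column = cn, roi = cn, channel = "signal")
    }
  })
}

#' Read a tabular trace file into a trace set
#'
#' Accepts CSV, TSV or XLSX (first sheet) tables with one time-or-frame
#' column plus per-ROI intensity columns. The frame interval is taken as the
#' median successive difference of the time column, or as `1 / frame_rate`
#' from the schema when only frame indices are present.
#'
#' @param path Path to the table.
#' @param schema A [trace_schema()]; the default expects a `time` column and
#'   `<roi>_G` / `<roi>_R` intensity columns.
#' @param meta Optional metadata list stored on the result.
#' @return A [trace_set()].
#' @export
read_trace_table <- function(path, schema = trace_schema(), meta = list()) {
  raw <- read_raw_table(path)
  cols <- names(raw)
  for (cn in cols) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop_synca(
          sprintf("non-numeric cell at row %d, column '%s'", bad[1], cn),
          "parse_error"
        )
      }
      raw[[cn]] <- num
    }
    if (anyNA(raw[[cn]])) {
      stop_synca(sprintf("missing value in column '%s'", cn), "format_error")
    }
  }
  if (!is.null(schema$time_col) && schema$time_col %in% cols) {
    tv <- raw[[schema$time_col]]
    dtv <- diff(tv)
    if (any(dtv <= 0)) stop_synca("time column is not strictly increasing", "timebase_error")
    dt <- median(dtv)
    data_cols <- setdiff(cols, schema$time_col)
  } else if (!is.null(schema$frame_rate)) {
    dt <- 1 / schema$frame_rate
    data_cols <- setdiff(cols, c("frame", schema$time_col))
  } else {
    stop_synca(
      paste0("time column '", schema$time_col, "' not found and no frame_rate given"),
      "timebase_error"
    )
  }
  cmap <- map_columns(data_cols, schema)
  nf <- nrow(raw)
  # preserve input column order of ROIs
  rois <- unique(cmap$roi)
  long <- purrr::map_dfr(rois, function(r) {
    sub <- cmap[cmap$roi == r, ]
    sig <- sub$column[sub$channel == "signal"]
    ref <- sub$column[sub$channel == "reference"]
    if (!length(sig)) stop_synca(paste0("ROI '", r, "' has no signal column"), "format_error")
    tibble(
      roi = r, frame = seq_len(nf) - 1L,
      signal = raw[[sig[1]]],
      reference = if (length(ref)) raw[[ref[1]]] else NA_real_
    )
  })
  if (all(is.na(long$reference))) long$reference <- NULL
  trace_set(long, frame_interval_s = dt, meta = meta)
}

#' Write a trace set to CSV
#'
#' Wide layout: `time` column plus `<roi>_G` (and `<roi>_R`) intensity
#' columns, re-readable with the default [trace_schema()].
#'
#' @param trace A [trace_set()].
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(trace, path) {
  t <- timebase(trace)
  out <- tibble(time = t)
  for (r in trace_rois(trace)) {
    d <- trace_roi(trace, r)
    out[[paste0(r, "_G")]] <- d$signal
    if ("reference" %in% names(d)) out[[paste0(r, "_R")]] <- d$reference
  }
  readr::write_csv(out, path)
  invisible(path)
}

event_table_cols <- c(
  "roi", "peak_index", "peak_time_s", "amplitude", "onset_time_s",
  "tau_rise_s", "tau_decay_s", "sum_df", "fit_amplitude",
  "fit_r2_rise", "fit_r2_decay", "snr", "provenance", "flags"
)

#' Write a detected-event table to CSV
#'
#' One row per event in a stable, documented column order
#' (roi, peak_index, peak_time_s, amplitude, onset_time_s, tau_rise_s,
#' tau_decay_s, sum_df, fit_amplitude, fit_r2_rise, fit_r2_decay, snr,
#' provenance, flags). An empty event set writes a header-only file.
#'
#' @param events Event tibble as returned by [quantify_events()].
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  ev <- as_tibble(events)
  for (cn in setdiff(event_table_cols, names(ev))) {
    ev[[cn]] <- if (cn %in% c("roi", "provenance", "flags")) NA_character_ else NA_real_
  }
  ev <- ev[, event_table_cols]
  ok <- try(readr::write_csv(ev, path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop_synca(paste0("cannot write event table: ", path), "io_error")
  }
  invisible(path)
}

#' Read back an event table written by [write_event_table()]
#'
#' @param path Path to the CSV.
#' @return Event tibble.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop_synca(paste0("file not found: ", path), "io_error")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    roi = "c", provenance = "c", flags = "c",
                    peak_index = "i", .default = "d"
                  ))
}

#' Infer and print the schema of a trace table
#'
#' Convenience for the command line: reports the inferred time column,
#' frame interval and ROI/channel mapping of a table.
#'
#' @param path Path to the table.
#' @param schema A [trace_schema()].
#' @return A list with `frame_interval_s`, `n_frames` and the column map,
#'   invisibly; prints a summary.
#' @export
validate_trace_table <- function(path, schema = trace_schema()) {
  ts <- read_trace_table(path, schema)
  info <- list(
    frame_interval_s = frame_interval(ts),
    n_frames = n_frames(ts),
    rois = trace_rois(ts),
    two_channel = "reference" %in% names(ts)
  )
  cat(sprintf(
    "%s: %d frames @ %.6g s/frame; %d ROI(s): %s; %s\n",
    basename(path), info$n_frames, info$frame_interval_s,
    length(info$rois), paste(info$rois, collapse = ", "),
    if (info$two_channel) "two-channel (G+R)" else "single-channel"
  ))
  invisible(info)
}
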