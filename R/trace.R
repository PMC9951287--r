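#' Construct a current trace
#'
#' A `current_trace` is a sampled ionic-current record together with its
#' acquisition metadata: the sampling interval, the analog low-pass cutoff
#' (if any), the applied potential and a free-text recording label.
#'
#' @param samples Numeric vector of current values (pA), in sample order.
#' @param sampling_interval Time per sample in microseconds. Must be > 0.
#' @param filter_cutoff Low-pass cutoff in kHz, or `NA` for an unfiltered
#'   record.
#' @param voltage Applied potential in mV (metadata only).
#' @param label Free-text recording identifier.
#'
#' @return An object of class `current_trace`: a list with fields
#'   `samples`, `sampling_interval`, `filter_cutoff`, `voltage`, `label`.
#'
#' @examples
#' tr <- current_trace(rnorm(2000, 115, 1.7), sampling_interval = 4)
#' tr
#' @export
current_trace <- function(samples, sampling_interval, filter_cutoff = NA_real_,
                          voltage = NA_real_, label = "trace") {
  samples <- as.double(samples)
  if (length(samples) < 1L) {
    abort("no samples: a current trace must contain at least one sample")
  }
  bad <- which(!is.finite(samples))
  if (length(bad) > 0L) {
    abort(sprintf("non-finite sample at index %d", bad[[1L]]))
  }
  sampling_interval <- as.double(sampling_interval)
  if (length(sampling_interval) != 1L || !is.finite(sampling_interval) ||
      sampling_interval <= 0) {
    abort("sampling_interval must be a single positive number (microseconds)")
  }
  structure(
    list(
      samples = samples,
      sampling_interval = sampling_interval,
      filter_cutoff = as.double(filter_cutoff),
      voltage = as.double(voltage),
      label = as.character(label)
    ),
    class = "current_trace"
  )
}

#' @export
print.current_trace <- function(x, ...) {
  dur_ms <- length(x$samples) * x$sampling_interval / US_PER_MS
  cat(sprintf(
    "<current_trace '%s': %d samples @ %g us (%.3g ms), %s, mean %.2f pA>\n",
    x$label, length(x$samples), x$sampling_interval, dur_ms,
    if (is.finite(x$filter_cutoff)) sprintf("%g kHz low-pass", x$filter_cutoff)
    else "unfiltered",
    mean(x$samples)
  ))
  invisible(x)
}

#' @export
length.current_trace <- function(x) length(x$samples)

#' Duration of a trace in seconds
#' @param trace A [current_trace()].
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) {
  length(trace$samples) * trace$sampling_interval / 1e6
}

is_current_trace <- function(x) inherits(x, "current_trace")

stopifnot_trace <- function(trace) {
  if (!is_current_trace(trace)) abort("expected a current_trace object")
  invisible(trace)
}

# ---- file formats -----------------------------------------------------------
#
# Both trace containers share one header dialect: "#key=value" lines closed by
# "#end_header". The tabular body is one current value per line under a
# "current_pa" column; the binary body is a contiguous little-endian float64
# array. Event tables are plain CSV with a fixed schema.

HEADER_END <- "#end_header"

format_header <- function(trace) {
  c(
    sprintf("#sampling_interval_us=%.10g", trace$sampling_interval),
    sprintf("#filter_cutoff_khz=%s",
            if (is.finite(trace$filter_cutoff))
              sprintf("%.10g", trace$filter_cutoff) else "NA"),
    sprintf("#voltage_mv=%s",
            if (is.finite(trace$voltage))
              sprintf("%.10g", trace$voltage) else "NA"),
    sprintf("#label=%s", trace$label),
    HEADER_END
  )
}

parse_header <- function(lines, path) {
  kv <- list()
  for (ln in lines) {
    ln <- sub("^#", "", ln)
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) abort(sprintf("unparseable header line in '%s': %s", path, ln))
    kv[[substr(ln, 1L, eq - 1L)]] <- substr(ln, eq + 1L, nchar(ln))
  }
  if (is.null(kv$sampling_interval_us)) {
    abort(sprintf("unparseable header in '%s': missing sampling_interval_us", path))
  }
  num_or_na <- function(x) if (is.null(x) || identical(x, "NA")) NA_real_ else as.double(x)
  list(
    sampling_interval = as.double(kv$sampling_interval_us),
    filter_cutoff = num_or_na(kv$filter_cutoff_khz),
    voltage = num_or_na(kv$voltage_mv),
    label = if (is.null(kv$label)) "trace" else kv$label
  )
}

#' Read a current trace from disk
#'
#' Supports two self-describing container formats written by [write_trace()]:
#' `"tabular"` (a `#key=value` metadata header followed by one current value
#' per line) and `"binary"` (the same header followed by a contiguous
#' little-endian float64 array). Reading Axon Binary Format (`"abf"`) is not
#' compiled into this package; requesting it raises a clear error so that
#' pipelines degrade gracefully.
#'
#' @param path File to read.
#' @param format_id One of `"tabular"`, `"binary"`, `"abf"`.
#' @return A [current_trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, format_id = c("tabular", "binary", "abf")) {
  format_id <- match.arg(format_id)
  if (format_id == "abf") {
    abort(paste(
      "ABF reading is not available in this build;",
      "convert the recording to the tabular or binary container first"
    ))
  }
  if (!file.exists(path)) abort(sprintf("missing file: '%s'", path))

  if (format_id == "tabular") {
    lines <- readLines(path)
    end <- match(HEADER_END, lines)
    if (is.na(end)) abort(sprintf("unparseable header in '%s': no %s", path, HEADER_END))
    meta <- parse_header(lines[seq_len(end - 1L)], path)
    body <- lines[-seq_len(end)]
    body <- body[nzchar(body)]
    if (length(body) == 0L || (length(body) == 1L && body[[1L]] == "current_pa")) {
      abort(sprintf("no samples in '%s'", path))
    }
    if (body[[1L]] == "current_pa") body <- body[-1L]
    samples <- suppressWarnings(as.double(body))
    bad <- which(!is.finite(samples))
    if (length(bad) > 0L) {
      abort(sprintf("non-finite sample at index %d in '%s'", bad[[1L]], path))
    }
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- character()
    repeat {
      ln <- readLines(con, n = 1L)
      if (length(ln) == 0L) abort(sprintf("unparseable header in '%s': no %s", path, HEADER_END))
      if (identical(ln, HEADER_END)) break
      hdr <- c(hdr, ln)
    }
    meta <- parse_header(hdr, path)
    n_line <- hdr[startsWith(hdr, "#n_samples=")]
    if (length(n_line) != 1L) abort(sprintf("unparseable header in '%s': missing n_samples", path))
    n <- as.integer(sub("#n_samples=", "", n_line, fixed = TRUE))
    if (is.na(n) || n < 1L) abort(sprintf("no samples in '%s'", path))
    samples <- readBin(con, "double", n = n, size = 8L, endian = "little")
    if (length(samples) != n) abort(sprintf("truncated binary body in '%s'", path))
    bad <- which(!is.finite(samples))
    if (length(bad) > 0L) {
      abort(sprintf("non-finite sample at index %d in '%s'", bad[[1L]], path))
    }
  }
  current_trace(samples, meta$sampling_interval, meta$filter_cutoff,
                meta$voltage, meta$label)
}

#' Write a current trace to disk
#'
#' @inheritParams read_trace
#' @param trace A [current_trace()].
#' @return The path written, invisibly usable in pipes.
#' @export
write_trace <- function(trace, path, format_id = c("tabular", "binary")) {
  stopifnot_trace(trace)
  format_id <- match.arg(format_id)
  if (format_id == "tabular") {
    lines <- c(format_header(trace), "current_pa",
               sprintf("%.10g", trace$samples))
    tryCatch(writeLines(lines, path),
             error = function(e) abort(sprintf("unwritable path: '%s'", path)))
  } else {
    con <- tryCatch(file(path, "wb"),
                    error = function(e) abort(sprintf("unwritable path: '%s'", path)))
    on.exit(close(con))
    hdr <- c(sprintf("#n_samples=%d", length(trace$samples)),
             format_header(trace))
    writeLines(hdr, con)
    writeBin(trace$samples, con, size = 8L, endian = "little")
  }
  invisible(path)
}

# ---- event tables -----------------------------------------------------------

EVENT_SCHEMA <- c(
  recording_id = "character",
  start_time = "double",   # us
  dwell = "double",        # us
  i_b = "double",          # pA
  normalized_blockade = "double",
  label = "character"
)

#' Write an event table to CSV
#'
#' The on-disk schema is fixed: `recording_id`, `start_time` (us), `dwell`
#' (us), `i_b` (pA), `normalized_blockade`, `label`. Extra columns present in
#' memory (sample indices, flags, truth labels) are dropped on write.
#'
#' @param events A tibble of events, one row per blockade.
#' @param path File to write.
#' @return The path written, invisibly.
#' @export
write_events <- function(events, path) {
  events <- tibble::as_tibble(events)
  missing_cols <- setdiff(names(EVENT_SCHEMA), names(events))
  # label is optional in memory
  if ("label" %in% missing_cols && nrow(events) >= 0L) {
    events$label <- NA_character_
    missing_cols <- setdiff(missing_cols, "label")
  }
  if (length(missing_cols) > 0L) {
    abort(sprintf("events table lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(events[names(EVENT_SCHEMA)], path)
  invisible(path)
}

#' Read an event table from CSV
#'
#' @param path File written by [write_events()].
#' @return A tibble with the fixed event schema.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing file: '%s'", path))
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(names(EVENT_SCHEMA), hdr)
  if (length(missing_cols) > 0L) {
    abort(sprintf("schema mismatch in '%s': missing column(s) %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  readr::read_csv(
    path,
    col_types = readr::cols(
      recording_id = readr::col_character(),
      start_time = readr::col_double(),
      dwell = readr::col_double(),
      i_b = readr::col_double(),
      normalized_blockade = readr::col_double(),
      label = readr::col_character()
    )
  )
}

#' Pool events from several recordings
#'
#' Events from different recordings can be pooled for ensemble fitting
#' because the normalized blockade is computed against each recording's own
#' open-pore baseline; pooling never rescales per-event features. Each
#' member of `recordings` must carry its own baseline estimate.
#'
#' @param recordings A named list; each element is a list with fields
#'   `events` (tibble) and `baseline` (a [baseline_estimate] as returned by
#'   [estimate_baseline()]).
#' @return A single tibble of events; `recording_id` is taken from the list
#'   names when the per-recording tables do not already set it.
#' @export
concatenate_recordings <- function(recordings) {
  if (length(recordings) == 0L) abort("no recordings supplied")
  ids <- names(recordings)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- sprintf("recording_%d", seq_along(recordings))
  }
  if (anyDuplicated(ids)) abort("recording ids must be unique")
  pooled <- purrr::map2(recordings, ids, function(rec, id) {
    if (is.null(rec$baseline) || !inherits(rec$baseline, "baseline_estimate")) {
      abort(sprintf("recording '%s' lacks a baseline estimate", id))
    }
    ev <- tibble::as_tibble(rec$events)
    if (!"recording_id" %in% names(ev) || all(is.na(ev$recording_id))) {
      ev$recording_id <- id
    }
    ev
  })
  dplyr::bind_rows(pooled)
}
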