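#' Estimate the open-pore baseline of a recording
#'
#' Iterative exclusion scheme: starting from robust seeds (median and
#' scaled MAD, so that even heavily blocked traces converge), the mean and
#' SD are recomputed over retained samples and all samples below
#' `mean - k_exclude * SD` are excluded, until both estimates move by less
#' than `tol` or `max_iter` is reached. Only the downward tail is excluded:
#' analyte blockades reduce the current at positive applied potential.
#'
#' @param trace A [current_trace()] of at least 1000 samples.
#' @param k_exclude Exclusion multiplier (default 5).
#' @param max_iter Maximum iterations.
#' @param tol Convergence tolerance in pA on both the mean and the SD.
#' @return A `baseline_estimate`: list with `i0` (pA), `delta` (pA),
#'   `n_samples_used`, `n_iter`, `converged`.
#' @examples
#' tr <- current_trace(rnorm(5000, 115, 1.7), 4)
#' estimate_baseline(tr)
#' @export
estimate_baseline <- function(trace, k_exclude = 5, max_iter = 50L,
                              tol = 1e-4) {
  stopifnot_trace(trace)
  x <- trace$samples
  if (length(x) < 1000L) {
    abort("baseline estimation needs at least 1000 samples")
  }
  if (k_exclude <= 0) abort("k_exclude must be > 0")
  i0 <- median(x)
  delta <- mad(x)
  converged <- FALSE
  n_used <- length(x)
  for (iter in seq_len(max_iter)) {
    keep <- x >= i0 - k_exclude * delta
    n_used <- sum(keep)
    if (n_used == 0L) {
      abort("baseline estimation retained no samples")
    }
    xi <- x[keep]
    i0_new <- mean(xi)
    delta_new <- if (n_used > 1L) sd(xi) else 0
    moved <- max(abs(i0_new - i0), abs(delta_new - delta))
    i0 <- i0_new
    delta <- delta_new
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }
  est <- new_baseline(i0, delta, n_used, iter, converged)
  if (!converged) {
    abort(
      sprintf("baseline estimation did not converge in %d iterations (last i0 = %.4f, delta = %.4f)",
              max_iter, i0, delta),
      class = "porepulse_baseline_nonconvergence",
      estimate = est
    )
  }
  if (est$i0 <= 0) abort("estimated open-pore current is not positive")
  est
}

new_baseline <- function(i0, delta, n_samples_used = NA_integer_,
                         n_iter = 0L, converged = TRUE) {
  structure(
    list(i0 = i0, delta = delta, n_samples_used = n_samples_used,
         n_iter = n_iter, converged = converged),
    class = "baseline_estimate"
  )
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("<baseline: i0 = %.3f pA, delta = %.3f pA (n = %d, %d iteration(s))>\n",
              x$i0, x$delta, x$n_samples_used, x$n_iter))
  invisible(x)
}

#' Normalized blockade level
#'
#' The fraction of the open-pore current suppressed during an event,
#' `(i0 - i_b) / i0`.
#'
#' @param i0 Open-pore current (pA), > 0.
#' @param i_b Mean blockade current of the event (pA).
#' @return Dimensionless blockade fraction (1 = full block, 0 = no block).
#' @export
normalized_blockade <- function(i0, i_b) {
  if (any(i0 <= 0)) abort("i0 must be > 0")
  (i0 - i_b) / i0
}

# Number of edge samples excluded from the blockade mean on filtered traces:
# the time for the filtered edge to settle from the threshold crossing to
# ~99% of a full step is about 0.11 ms at 5 kHz for the 4-pole Bessel, i.e.
# 550 us.kHz / cutoff.
default_edge_exclude <- function(trace) {
  if (!is.finite(trace$filter_cutoff)) return(0L)
  as.integer(ceiling((550 / trace$filter_cutoff) / trace$sampling_interval))
}

#' Measure dwell and mean blockade current of one event
#'
#' Dwell is the boundary span times the sampling interval. The blockade
#' current `i_b` is the mean over the event interior: boundary samples are
#' excluded, plus `edge_exclude` further samples per side on filtered traces
#' so the filter-settling flanks do not bias the level. When the guarded
#' interior would be empty the guard shrinks, and a 2-sample event falls
#' back to the mean of both samples.
#'
#' @param trace A [current_trace()].
#' @param start,end Half-open sample interval `[start, end)`, 1-based.
#' @param baseline A `baseline_estimate` (used only for validation here).
#' @param edge_exclude Extra samples excluded per side; `NULL` for the
#'   filter-based default.
#' @return A list with `dwell` (us) and `i_b` (pA).
#' @export
measure_event <- function(trace, start, end, baseline = NULL,
                          edge_exclude = NULL) {
  stopifnot_trace(trace)
  if (end <= start) abort("empty event interval")
  if (start < 1L || end > length(trace$samples) + 1L) {
    abort("event boundaries outside trace")
  }
  if (is.null(edge_exclude)) edge_exclude <- default_edge_exclude(trace)
  dwell <- (end - start) * trace$sampling_interval
  i_b <- interior_mean(trace$samples, start, end, edge_exclude)
  list(dwell = dwell, i_b = i_b)
}

# mean over [start, end) with boundary exclusion and a shrinking edge guard
interior_mean <- function(x, start, end, guard) {
  n <- end - start
  if (n <= 2L) return(mean(x[start:(end - 1L)]))
  g <- min(guard, (n - 3L) %/% 2L)
  mean(x[(start + 1L + g):(end - 2L - g)])
}

#' Detect blockade events by the threshold rule
#'
#' An event is each maximal run of at least `min_samples` consecutive
#' samples below the threshold `i0 - k * delta`. Boundaries sit at the
#' first and last sub-threshold sample (half-open interval); events
#' touching either end of the trace are discarded because their dwell is
#' unknowable. Upward excursions are ignored.
#'
#' On filtered traces the threshold crossings of a deep event sit
#' asymmetrically on the rising and falling flanks, which stretches the
#' apparent dwell by roughly the filter rise time. Setting
#' `refine_midpoint = TRUE` re-times each boundary at the 50%-amplitude
#' crossing of the event's own depth (with linear sub-sample
#' interpolation), which cancels that broadening; the reported sample
#' indices stay at the threshold crossings.
#'
#' @param trace A [current_trace()].
#' @param baseline A `baseline_estimate` from [estimate_baseline()].
#' @param k Threshold multiplier (default 5).
#' @param min_samples Minimum run length in samples (default 2).
#' @param refine_midpoint Refine dwell to 50%-amplitude crossings.
#' @param edge_exclude Per-side guard for the blockade mean; `NULL` for the
#'   filter-based default.
#' @param recording_id Recording identifier stored with each event.
#' @return A tibble with one row per event: `recording_id`, `start_index`,
#'   `end_index` (half-open), `start_time` (us), `dwell` (us), `i_b` (pA),
#'   `normalized_blockade`, `flagged` (blockade <= 0, kept but marked) and
#'   `label` (`NA`, reserved for population assignment).
#' @export
detect_events <- function(trace, baseline, k = 5, min_samples = 2L,
                          refine_midpoint = FALSE, edge_exclude = NULL,
                          recording_id = trace$label) {
  stopifnot_trace(trace)
  if (!inherits(baseline, "baseline_estimate")) {
    abort("baseline must be a baseline_estimate")
  }
  if (k <= 0) abort("k must be > 0")
  if (min_samples < 1L) abort("min_samples must be >= 1")
  if (is.null(edge_exclude)) edge_exclude <- default_edge_exclude(trace)
  x <- trace$samples
  dt <- trace$sampling_interval
  threshold <- baseline$i0 - k * baseline$delta

  below <- x < threshold
  r <- rle(below)
  ends_all <- cumsum(r$lengths)
  starts_all <- ends_all - r$lengths + 1L
  sel <- r$values & r$lengths >= min_samples
  start <- starts_all[sel]
  end <- ends_all[sel] + 1L          # half-open
  # discard events touching the trace ends
  keep <- start > 1L & end <= length(x)
  start <- start[keep]
  end <- end[keep]
  if (length(start) == 0L) {
    return(empty_events(recording_id))
  }

  # interior means via cumulative sums (O(1) per event)
  cx <- c(0, cumsum(x))
  seg_mean <- function(a, b) (cx[b] - cx[a]) / (b - a)  # mean over [a, b)
  n_ev <- length(start)
  i_b <- numeric(n_ev)
  for (j in seq_len(n_ev)) {
    n <- end[[j]] - start[[j]]
    if (n <= 2L) {
      i_b[[j]] <- seg_mean(start[[j]], end[[j]])
    } else {
      g <- min(edge_exclude, (n - 3L) %/% 2L)
      i_b[[j]] <- seg_mean(start[[j]] + 1L + g, end[[j]] - 1L - g)
    }
  }

  dwell <- (end - start) * dt
  if (refine_midpoint) {
    dwell <- refine_dwell_midpoint(x, start, end, baseline$i0, i_b, dt,
                                   threshold)
  }

  nb <- normalized_blockade(baseline$i0, i_b)
  tibble::tibble(
    recording_id = recording_id,
    start_index = start,
    end_index = end,
    start_time = (start - 1L) * dt,
    dwell = dwell,
    i_b = i_b,
    normalized_blockade = nb,
    flagged = nb <= 0,
    label = NA_character_
  )
}

empty_events <- function(recording_id) {
  tibble::tibble(
    recording_id = character(), start_index = integer(),
    end_index = integer(), start_time = double(), dwell = double(),
    i_b = double(), normalized_blockade = double(), flagged = logical(),
    label = character()
  )
}

# Re-times each event boundary at the crossing of the 50%-amplitude level
# of that event's own depth, searching outward from the threshold
# crossings, with linear sub-sample interpolation. Falls back to the
# threshold dwell when no half-level crossing is found nearby.
refine_dwell_midpoint <- function(x, start, end, i0, i_b, dt, threshold,
                                  window = 64L) {
  n_ev <- length(start)
  dwell <- (end - start) * dt
  nx <- length(x)
  for (j in seq_len(n_ev)) {
    half <- i0 - (i0 - i_b[[j]]) / 2
    if (half >= threshold) next   # event too shallow for the half level to
                                  # sit below the threshold: keep as is
    # entry: first crossing below `half` at/after the first sub-threshold
    # sample; the signal is still descending there, so scan forward
    a <- start[[j]]
    lim_a <- min(end[[j]] - 1L, a + window)
    t_entry <- NA_real_
    for (i in a:lim_a) {
      if (x[[i]] < half) {
        if (i == 1L) break
        x0 <- x[[i - 1L]]
        frac <- if (x0 == x[[i]]) 0 else (x0 - half) / (x0 - x[[i]])
        t_entry <- (i - 2L + frac) * dt
        break
      }
    }
    # exit: last sample below `half` at/before the last sub-threshold
    # sample; scan backward
    b <- end[[j]] - 1L
    lim_b <- max(start[[j]], b - window)
    t_exit <- NA_real_
    for (i in b:lim_b) {
      if (x[[i]] < half) {
        if (i == nx) break
        x1 <- x[[i + 1L]]
        frac <- if (x1 == x[[i]]) 0 else (x1 - half) / (x1 - x[[i]])
        t_exit <- (i - frac) * dt
        break
      }
    }
    if (is.finite(t_entry) && is.finite(t_exit) && t_exit > t_entry) {
      dwell[[j]] <- t_exit - t_entry
    }
  }
  dwell
}

#' Separate translocations from bumping events
#'
#' Bumping events -- molecules that approach the pore mouth without
#' entering -- are brief and shallow; translocation or interaction events
#' have dwell times beyond 200 us and deeper blockades. Retains events with
#' `dwell > min_dwell` and, when given, `normalized_blockade >=
#' min_blockade`; row order is preserved.
#'
#' @param events Event tibble from [detect_events()].
#' @param min_dwell Minimum dwell in us (strict, default 200).
#' @param min_blockade Optional minimum normalized blockade (inclusive).
#' @return The retained subset of `events`.
#' @export
filter_translocations <- function(events, min_dwell = 200,
                                  min_blockade = NULL) {
  events <- tibble::as_tibble(events)
  keep <- events$dwell > min_dwell
  if (!is.null(min_blockade)) {
    keep <- keep & events$normalized_blockade >= min_blockade
  }
  events[keep, ]
}
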