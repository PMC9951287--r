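# Shared fixtures, all generated in code.

# Event table drawn directly from population models (no trace rendering):
# normalized_blockade / dwell carry the generating values, label the truth.
make_event_table <- function(pops, n_per, seed = 1L) {
  set.seed(seed)
  pops <- tibble::as_tibble(pops)
  if (length(n_per) == 1L) n_per <- rep(n_per, nrow(pops))
  rows <- lapply(seq_len(nrow(pops)), function(i) {
    ev <- sample_population_events(pops[i, ], n_per[[i]])
    tibble::tibble(
      recording_id = "synthetic",
      start_index = NA_integer_, end_index = NA_integer_,
      start_time = NA_real_, dwell = ev$dwell, i_b = NA_real_,
      normalized_blockade = ev$blockade, flagged = FALSE, label = ev$name
    )
  })
  dplyr::bind_rows(rows)
}

# Rectangular events injected into a known baseline; returns the trace and
# the ground-truth sample intervals (half-open).
make_injected_trace <- function(n_events = 10L, i0 = 115, noise_sd = 1,
                                depth = 10, dwell_samples = 250L,
                                spacing_samples = 2500L, dt = 4,
                                seed = 1L, lead = 1000L) {
  set.seed(seed)
  n <- lead + n_events * spacing_samples + lead
  x <- rnorm(n, i0, noise_sd)
  starts <- lead + (seq_len(n_events) - 1L) * spacing_samples + 1L
  ends <- starts + dwell_samples            # half-open
  for (j in seq_len(n_events)) {
    idx <- starts[[j]]:(ends[[j]] - 1L)
    x[idx] <- x[idx] - depth * noise_sd
  }
  list(trace = current_trace(x, dt, label = "injected"),
       start = starts, end = ends)
}

# Independent exhaustive event scan: a plain sample-by-sample loop,
# deliberately naive, used as the oracle for detect_events.
brute_force_scan <- function(samples, threshold, min_samples) {
  n <- length(samples)
  starts <- integer()
  ends <- integer()
  run_start <- NA_integer_
  for (i in seq_len(n)) {
    if (samples[[i]] < threshold) {
      if (is.na(run_start)) run_start <- i
    } else {
      if (!is.na(run_start)) {
        if (i - run_start >= min_samples) {
          starts <- c(starts, run_start)
          ends <- c(ends, i)
        }
        run_start <- NA_integer_
      }
    }
  }
  if (!is.na(run_start) && n + 1L - run_start >= min_samples) {
    starts <- c(starts, run_start)
    ends <- c(ends, n + 1L)
  }
  keep <- starts > 1L & ends <= n
  list(start = starts[keep], end = ends[keep])
}
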