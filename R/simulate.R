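#' Simulation configuration
#'
#' Collects everything needed to generate one synthetic recording: the
#' open-pore level and its Gaussian noise, acquisition settings (sampling
#' interval and low-pass cutoff), the recording duration, the translocating
#' populations, the bumping population, and the seed. Defaults reproduce
#' typical wild-type aerolysin acquisition: ~115 pA open pore, 1.7 pA noise,
#' 4 us sampling, 5 kHz 4-pole Bessel filtering.
#'
#' @param populations Population tibble (see [default_population_library()]).
#' @param duration Recording duration in seconds.
#' @param i0 Open-pore current in pA.
#' @param noise_sd Baseline Gaussian noise SD in pA (before filtering).
#' @param sampling_interval Sampling interval in us.
#' @param filter_cutoff Low-pass cutoff in kHz; `NA` disables filtering.
#' @param bumping A one-row population for bumping events, or `NULL` to omit
#'   them. By default the bumping rate equals the summed translocation rate.
#' @param voltage Applied potential in mV (metadata).
#' @param seed Integer seed; the whole recording is reproducible from it.
#' @param label Recording label.
#' @return A `simulation_config` object (a validated list).
#' @export
simulation_config <- function(populations = default_population_library(),
                              duration = 10,
                              i0 = 115, noise_sd = 1.7,
                              sampling_interval = 4, filter_cutoff = 5,
                              bumping = bumping_population(sum(populations$rate)),
                              voltage = 50, seed = 1L,
                              label = "simulated") {
  if (!is.finite(i0) || i0 <= 0) abort("i0 must be > 0 (pA)")
  if (!is.finite(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0 (pA)")
  if (!is.finite(duration) || duration <= 0) abort("duration must be > 0 (s)")
  if (!is.finite(sampling_interval) || sampling_interval <= 0) {
    abort("sampling_interval must be > 0 (us)")
  }
  populations <- tibble::as_tibble(populations)
  if (nrow(populations) == 0L && is.null(bumping)) {
    warn("baseline-only simulation: no populations supplied")
  }
  for (i in seq_len(nrow(populations))) validate_population(populations[i, ])
  if (!is.null(bumping)) validate_population(bumping)
  structure(
    list(
      populations = populations, duration = duration, i0 = i0,
      noise_sd = noise_sd, sampling_interval = sampling_interval,
      filter_cutoff = as.double(filter_cutoff), bumping = bumping,
      voltage = voltage, seed = as.integer(seed), label = label
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config '%s': %g s @ %g us, i0 %g pA (noise %g pA), %s, %d population(s)%s, seed %d>\n",
    x$label, x$duration, x$sampling_interval, x$i0, x$noise_sd,
    if (is.finite(x$filter_cutoff)) sprintf("%g kHz Bessel", x$filter_cutoff)
    else "unfiltered",
    nrow(x$populations), if (is.null(x$bumping)) "" else " + bumping", x$seed
  ))
  invisible(x)
}

#' Serialize / restore a simulation configuration
#'
#' Structured-text (YAML) round trip for provenance alongside generated data.
#'
#' @param config A [simulation_config()].
#' @param path File to write or read.
#' @return `write_simulation_config()` the path, invisibly;
#'   `read_simulation_config()` the restored config.
#' @export
write_simulation_config <- function(config, path) {
  x <- unclass(config)
  x$populations <- as.list(as.data.frame(x$populations))
  x$bumping <- if (is.null(x$bumping)) NULL else as.list(as.data.frame(x$bumping))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  simulation_config(
    populations = tibble::as_tibble(x$populations),
    duration = x$duration, i0 = x$i0, noise_sd = x$noise_sd,
    sampling_interval = x$sampling_interval,
    filter_cutoff = if (is.null(x$filter_cutoff)) NA_real_ else x$filter_cutoff,
    bumping = if (is.null(x$bumping)) NULL else tibble::as_tibble(x$bumping),
    voltage = x$voltage, seed = x$seed, label = x$label
  )
}

# ---- low-pass filter --------------------------------------------------------

# 4th-order Bessel analog prototype poles, normalized so the magnitude
# response is -3 dB at 1 rad/s.
BESSEL4_POLES <- c(
  complex(real = -0.99520876, imaginary =  1.25710574),
  complex(real = -1.37006783, imaginary =  0.41024972),
  complex(real = -1.37006783, imaginary = -0.41024972),
  complex(real = -0.99520876, imaginary = -1.25710574)
)

#' Digital 4-pole Bessel low-pass filter coefficients
#'
#' Bilinear transform (with cutoff prewarping) of the magnitude-normalized
#' 4th-order Bessel analog prototype, the standard anti-aliasing filter of
#' patch-clamp amplifiers. Coefficients are normalized to exactly unity DC
#' gain so filtering never shifts the open-pore level.
#'
#' @param cutoff_khz -3 dB cutoff in kHz.
#' @param sampling_interval Sampling interval in us.
#' @return A list with numerator `b` and denominator `a` coefficients.
#' @export
bessel_lowpass <- function(cutoff_khz, sampling_interval) {
  fs <- 1e6 / sampling_interval            # Hz
  fc <- cutoff_khz * 1e3
  if (fc <= 0 || fc >= fs / 2) abort("cutoff must lie in (0, Nyquist)")
  T <- 1 / fs
  wc <- 2 / T * tan(pi * fc * T)           # prewarped analog cutoff
  pa <- BESSEL4_POLES * wc
  ka <- Re(prod(-pa))
  arma <- signal::as.Arma(signal::bilinear(Sz = NULL, Sp = pa, Sg = ka, T = T))
  b <- Re(arma$b)
  a <- Re(arma$a)
  b <- b * sum(a) / sum(b)                 # force unity DC gain
  list(b = b, a = a)
}

#' Apply the Bessel low-pass filter to a trace
#'
#' One-pass (causal) IIR filtering, as in the acquisition chain it mimics.
#' The constant group delay shifts all features equally and so cancels out
#' of dwell measurements.
#'
#' @param trace A [current_trace()].
#' @param cutoff_khz Cutoff in kHz; defaults to the trace's `filter_cutoff`.
#' @return A filtered [current_trace()] with `filter_cutoff` set.
#' @export
apply_lowpass <- function(trace, cutoff_khz = trace$filter_cutoff) {
  stopifnot_trace(trace)
  if (!is.finite(cutoff_khz)) return(trace)
  coef <- bessel_lowpass(cutoff_khz, trace$sampling_interval)
  # prepend a pad at the initial level so the filter starts settled
  pad <- rep(trace$samples[[1L]], 64L)
  y <- as.numeric(signal::filter(coef$b, coef$a, c(pad, trace$samples)))
  current_trace(y[-seq_along(pad)], trace$sampling_interval,
                filter_cutoff = cutoff_khz, voltage = trace$voltage,
                label = trace$label)
}

# ---- rendering --------------------------------------------------------------

validate_schedule <- function(truth, duration_us) {
  truth <- tibble::as_tibble(truth)
  needed <- c("start_time", "dwell", "blockade")
  missing_cols <- setdiff(needed, names(truth))
  if (length(missing_cols) > 0L) {
    abort(sprintf("ground truth lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(truth) == 0L) return(truth)
  truth <- truth[order(truth$start_time), ]
  ends <- truth$start_time + truth$dwell
  if (any(truth$start_time < 0) || any(ends > duration_us)) {
    abort("event extends past the recording duration")
  }
  if (nrow(truth) > 1L &&
      any(truth$start_time[-1L] < ends[-nrow(truth)])) {
    abort("overlapping events in schedule")
  }
  truth
}

#' Render a current trace from a ground-truth event schedule
#'
#' Baseline samples are `Normal(i0, noise_sd)`; during an event of blockade
#' `b` the level drops to `i0 * (1 - b)` with the same additive noise
#' (events are rectangular: the per-event mean blockade is the quantity the
#' analysis extracts, so intra-event structure beyond noise is not modeled).
#' The assembled two-level signal is then low-pass filtered at the
#' configured cutoff.
#'
#' @param truth Tibble with `start_time` (us), `dwell` (us), `blockade`;
#'   events must be non-overlapping and inside the duration.
#' @param config A [simulation_config()].
#' @return A [current_trace()].
#' @export
render_trace <- function(truth, config) {
  if (!inherits(config, "simulation_config")) {
    abort("config must be a simulation_config")
  }
  dt <- config$sampling_interval
  duration_us <- config$duration * 1e6
  truth <- validate_schedule(truth, duration_us)
  n <- floor(duration_us / dt)
  x <- rnorm(n, config$i0, config$noise_sd)
  if (nrow(truth) > 0L) {
    i_from <- pmax(1L, as.integer(round(truth$start_time / dt)) + 1L)
    i_to <- pmin(n, as.integer(round((truth$start_time + truth$dwell) / dt)))
    drop_amt <- config$i0 * truth$blockade
    for (j in seq_len(nrow(truth))) {
      if (i_to[[j]] >= i_from[[j]]) {
        x[i_from[[j]]:i_to[[j]]] <- x[i_from[[j]]:i_to[[j]]] - drop_amt[[j]]
      }
    }
  }
  tr <- current_trace(x, dt, filter_cutoff = NA_real_,
                      voltage = config$voltage, label = config$label)
  apply_lowpass(tr, config$filter_cutoff)
}

# Places events of given dwells uniformly in (margin, duration - margin),
# redrawing the start of any event that overlaps its predecessor until the
# arrangement is overlap-free. Each start stays paired with its own dwell.
# A minimum inter-event gap of 8 sampling intervals (at 4 us sampling) keeps
# threshold runs of adjacent events separable after filtering.
place_events <- function(dwell_us, duration_us, margin_us, gap_us = 32,
                         max_iter = 1000L) {
  n <- length(dwell_us)
  if (n == 0L) return(numeric())
  span <- duration_us - 2 * margin_us - dwell_us
  if (any(span < 0)) abort("an event is longer than the recording")
  start <- margin_us + runif(n) * span
  for (iter in seq_len(max_iter)) {
    ord <- order(start)
    s <- start[ord]
    d <- dwell_us[ord]
    bad <- which(s[-1L] < (s + d + gap_us)[-n])
    if (length(bad) == 0L) return(start)
    redraw <- ord[bad + 1L]
    start[redraw] <- margin_us + runif(length(redraw)) * span[redraw]
  }
  abort("could not place events without overlap; reduce rates or duration")
}

#' Simulate a complete recording with ground truth
#'
#' Per population, the event count is Poisson with mean `rate * duration`;
#' per-event dwell and blockade are drawn by [sample_population_events()];
#' events are placed uniformly in time with overlap rejection (rejected
#' arrivals are redrawn, preserving the expected counts). The same seed
#' reproduces the identical trace and truth bit for bit. Draw order is
#' documented and fixed: per-population counts, then per-population event
#' parameters (library order, bumping last), then placement, then noise.
#'
#' @param config A [simulation_config()].
#' @return A list with `trace` (a [current_trace()]) and `truth` (a tibble
#'   with `population`, `start_time` us, `dwell` us, `blockade`, sorted by
#'   start time).
#' @examples
#' cfg <- simulation_config(default_population_library()[2, ],
#'                          duration = 0.5, seed = 42)
#' rec <- simulate_recording(cfg)
#' rec$trace
#' @export
simulate_recording <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("config must be a simulation_config")
  }
  pops <- config$populations
  if (!is.null(config$bumping)) pops <- dplyr::bind_rows(pops, config$bumping)
  if (nrow(pops) > 0L) {
    mean_dwell_ms <- pops$dwell_mode * exp(1.5 * pops$dwell_sigma^2)
    occupancy <- sum(pops$rate * mean_dwell_ms) / 1e3
    if (occupancy > 0.5) {
      abort(sprintf(
        "expected pore occupancy %.2f exceeds 0.5; non-overlapping placement infeasible",
        occupancy))
    }
  }
  set.seed(config$seed)
  counts <- rpois(nrow(pops), pops$rate * config$duration)
  events <- purrr::map2(seq_len(nrow(pops)), counts, function(i, n) {
    sample_population_events(pops[i, ], n)
  })
  events <- dplyr::bind_rows(events)
  duration_us <- config$duration * 1e6
  margin_us <- 50 * config$sampling_interval
  if (nrow(events) > 0L) {
    # placement is joint across populations so no two events overlap
    events$start_time <- place_events(events$dwell, duration_us, margin_us)
    events <- events[order(events$start_time), ]
  } else {
    events$start_time <- numeric()
  }
  truth <- tibble::tibble(
    population = events$name, start_time = events$start_time,
    dwell = events$dwell, blockade = events$blockade
  )
  trace <- render_trace(truth, config)
  list(trace = trace, truth = truth)
}

#' Write ground truth to CSV
#'
#' Truth tables use `true_`-prefixed column names so they can never be
#' mistaken for measured event tables.
#'
#' @param truth Truth tibble from [simulate_recording()].
#' @param path File to write.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- tibble::tibble(
    true_population = truth$population,
    true_start_time = truth$start_time,
    true_dwell = truth$dwell,
    true_blockade = truth$blockade
  )
  readr::write_csv(out, path)
  invisible(path)
}
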