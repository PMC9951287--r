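test_that("baseline estimation recovers clean and contaminated baselines", {
  # constant trace: exact estimate with zero spread
  const <- current_trace(rep(115, 2000), 4)
  bl <- estimate_baseline(const)
  expect_equal(bl$i0, 115)
  expect_equal(bl$delta, 0)

  # pure Gaussian baseline: recovery within 3 standard errors
  set.seed(21)
  n <- 1e6
  tr <- current_trace(rnorm(n, 114.98, 1.67), 4)
  bl <- estimate_baseline(tr)
  expect_lt(abs(bl$i0 - 114.98), 3 * 1.67 / sqrt(n))
  expect_lt(abs(bl$delta - 1.67), 3 * 1.67 / sqrt(2 * n) + 0.002)

  # 10% of samples inside deep events must not drag the baseline down
  set.seed(22)
  x <- rnorm(2e5, 114.98, 1.67)
  ev_idx <- 1:(0.1 * length(x))
  x[ev_idx] <- x[ev_idx] - 0.6 * 114.98
  bl_cont <- estimate_baseline(current_trace(x, 4))
  expect_lt(abs(bl_cont$i0 - 114.98), 0.5)

  expect_error(estimate_baseline(current_trace(rep(1, 10), 4)),
               "at least 1000")
  expect_error(estimate_baseline(const, k_exclude = 0), "k_exclude")
})

test_that("threshold detection bijects with injected ground truth", {
  inj <- make_injected_trace(n_events = 10L, depth = 10, dwell_samples = 250L,
                             spacing_samples = 2500L)
  bl <- estimate_baseline(inj$trace)
  ev <- detect_events(inj$trace, bl)
  expect_identical(nrow(ev), 10L)
  # boundaries within 2 samples of the injected edges, dwell within 8 us
  expect_true(all(abs(ev$start_index - inj$start) <= 2))
  expect_true(all(abs(ev$end_index - inj$end) <= 2))
  expect_true(all(abs(ev$dwell - 250 * 4) <= 2 * 4))

  # constant baseline trace: nothing to detect
  const <- current_trace(rep(115, 5000), 4)
  expect_identical(nrow(detect_events(const, estimate_baseline(const))), 0L)

  expect_error(detect_events(inj$trace, bl, k = 0), "k must be")
})

test_that("shallow events are suppressed consistently with run statistics", {
  # depth 3*delta with threshold at 5*delta: a detection needs >= 2
  # consecutive noise excursions below -2*delta; the run-statistics oracle
  # gives the per-event detection probability
  dwell_samples <- 250L
  inj <- make_injected_trace(n_events = 200L, depth = 3, noise_sd = 1,
                             dwell_samples = dwell_samples,
                             spacing_samples = 1000L, seed = 31)
  bl <- porepulse:::new_baseline(115, 1)
  ev <- detect_events(inj$trace, bl, k = 5)
  frac <- nrow(ev) / 200
  p <- pnorm(-2)
  oracle <- 1 - (1 - p^2)^(dwell_samples - 1L)   # ~0.12
  expect_lt(abs(frac - oracle), 3 * sqrt(oracle * (1 - oracle) / 200) + 0.02)
  expect_lt(frac, 0.25)   # far below full detection
})

test_that("detection equals an independent brute-force scan", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(5e4, 115, 1.7)
    # sprinkle a few events of varying depth so both branches are exercised
    starts <- seq(2000, 45000, by = 5000)
    for (s in starts) x[s:(s + 150)] <- x[s:(s + 150)] - runif(1, 5, 60)
    tr <- current_trace(x, 4)
    bl <- estimate_baseline(tr)
    ev <- detect_events(tr, bl, k = 5, min_samples = 2L)
    oracle <- brute_force_scan(x, bl$i0 - 5 * bl$delta, 2L)
    expect_identical(ev$start_index, oracle$start)
    expect_identical(ev$end_index, oracle$end)
  }
})

test_that("raising the threshold multiplier never adds events", {
  # noiseless trace with a spread of depths: deterministic counts
  x <- rep(115, 5e4)
  depths <- rep(c(4, 8, 12, 20, 30), 6)
  starts <- seq(1000, by = 1500, length.out = length(depths))
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + 60)
    x[idx] <- x[idx] - depths[j]
  }
  bl <- porepulse:::new_baseline(115, 1.7)
  tr <- current_trace(x, 4)
  counts <- vapply(c(2, 3, 4, 5, 6, 8, 15, 20), function(k) {
    nrow(detect_events(tr, bl, k = k))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[[1]], 30)   # every depth above 2 * 1.7 pA
  expect_identical(counts[[8]], 0)    # threshold deeper than every event

  # with Gaussian noise and clearly deep events the ordering still holds
  set.seed(41)
  xn <- rnorm(1e5, 115, 1.7)
  for (s in seq(1000, 9.5e4, by = 2000)) xn[s:(s + 60)] <- xn[s:(s + 60)] - 50
  trn <- current_trace(xn, 4)
  bln <- estimate_baseline(trn)
  counts_n <- vapply(c(3, 5, 8, 12), function(k) {
    nrow(detect_events(trn, bln, k = k))
  }, numeric(1))
  expect_true(all(diff(counts_n) <= 0))
})

test_that("event measurement follows the interior rule", {
  # 250 samples at 4 us -> dwell 1000 us; interior excludes boundaries
  x <- rep(115, 2000)
  x[501:750] <- 42.55
  tr <- current_trace(x, 4)
  m <- measure_event(tr, 501L, 751L)
  expect_equal(m$dwell, 1000)
  expect_equal(m$i_b, 42.55)

  # boundary samples are excluded when an interior exists
  x2 <- rep(115, 2000)
  x2[500] <- 80          # partial boundary samples
  x2[505] <- 80
  x2[501:504] <- 40
  m2 <- measure_event(current_trace(x2, 4), 500L, 506L)
  expect_equal(m2$i_b, 40)

  # 2-sample event: interior exclusion is waived
  x3 <- rep(115, 2000)
  x3[600:601] <- c(50, 60)
  m3 <- measure_event(current_trace(x3, 4), 600L, 602L)
  expect_equal(m3$i_b, 55)

  expect_error(measure_event(tr, 10L, 10L), "empty event interval")
  expect_error(measure_event(tr, 0L, 5L), "outside trace")
})

test_that("normalized blockade is the fractional current drop", {
  expect_equal(normalized_blockade(115, 115), 0)
  expect_equal(normalized_blockade(115, 0), 1)
  expect_equal(normalized_blockade(114.98, 42.54), 0.630, tolerance = 5e-4)
  expect_error(normalized_blockade(0, 10), "i0 must be")
})

test_that("translocation filtering separates bumping by dwell", {
  lib <- default_population_library()
  ev <- make_event_table(dplyr::bind_rows(lib, bumping_population()),
                         1000, seed = 51)
  kept <- filter_translocations(ev)
  # all short bumping events go; >99% of true translocations stay
  expect_true(all(kept$dwell > 200))
  tr_labels <- ev$label != "bumping"
  expect_gt(sum(kept$label != "bumping") / sum(tr_labels), 0.99)
  expect_lt(mean(kept$label == "bumping"), 0.01)

  # degenerate bounds
  expect_identical(nrow(filter_translocations(ev[ev$dwell < 200, ])), 0L)
  expect_equal(filter_translocations(ev, min_dwell = 0), ev)

  # optional blockade bound
  kept2 <- filter_translocations(ev, min_blockade = 0.5)
  expect_true(all(kept2$normalized_blockade >= 0.5))
})

test_that("detection completeness holds on clean filtered traces", {
  # full pipeline on a filtered synthetic recording: every true
  # translocation has exactly one detected counterpart and dwell errors
  # stay within 2 samples + the filter rise time
  pop <- population_model("X", 0.5, 0.01, 2, rate = 15)
  cfg <- simulation_config(pop, duration = 4, bumping = NULL, seed = 61)
  rec <- simulate_recording(cfg)
  bl <- estimate_baseline(rec$trace)
  ev <- detect_events(rec$trace, bl, refine_midpoint = TRUE)
  ev <- filter_translocations(ev, min_dwell = 150)
  truth <- rec$truth

  expect_identical(nrow(ev), nrow(truth))
  # match by order (both time-sorted) and compare dwells
  err_us <- abs(ev$dwell - truth$dwell)
  expect_lt(max(err_us), 2 * 4 + 70)
  # with midpoint refinement the typical error is well under a sample pair
  expect_lt(median(err_us), 8)
  # start positions agree to within the filter group delay (~100 us)
  expect_lt(max(abs(ev$start_time - truth$start_time)), 150)
})

test_that("pipeline blockade recovery is unbiased for a single population", {
  pop <- population_model("X", 0.5, 0.01, 1.5, rate = 25)
  cfg <- simulation_config(pop, duration = 50, bumping = NULL, seed = 71)
  rec <- simulate_recording(cfg)
  bl <- estimate_baseline(rec$trace)
  ev <- filter_translocations(detect_events(rec$trace, bl,
                                            refine_midpoint = TRUE))
  expect_gt(nrow(ev), 1000)
  expect_lt(abs(mean(ev$normalized_blockade) - mean(rec$truth$blockade)),
            0.005)
})
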