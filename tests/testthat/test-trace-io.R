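test_that("tabular traces parse, including the two-row minimal file", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#sampling_interval_us=4", "#end_header",
               "current_pa", "115.0", "114.8"), path)
  tr <- read_trace(path, "tabular")
  expect_s3_class(tr, "current_trace")
  expect_identical(length(tr), 2L)
  expect_equal(tr$samples, c(115.0, 114.8))
  expect_equal(tr$sampling_interval, 4)
})

test_that("degenerate and malformed trace files are rejected", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#sampling_interval_us=4", "#end_header", "current_pa"), empty)
  expect_error(read_trace(empty, "tabular"), "no samples")

  expect_error(read_trace(withr::local_tempfile(), "tabular"), "missing file")

  no_interval <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#label=x", "#end_header", "current_pa", "1"), no_interval)
  expect_error(read_trace(no_interval, "tabular"), "sampling_interval")

  nonfinite <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#sampling_interval_us=4", "#end_header",
               "current_pa", "115", "oops", "114"), nonfinite)
  expect_error(read_trace(nonfinite, "tabular"), "non-finite sample at index 2")

  expect_error(current_trace(numeric(), 4), "no samples")
  expect_error(current_trace(c(1, NA), 4), "non-finite")
  expect_error(current_trace(1:5, 0), "sampling_interval")
})

test_that("trace round trips preserve samples and metadata", {
  set.seed(42)
  tr <- current_trace(rnorm(1000, 115, 1.7), 4, filter_cutoff = 5,
                      voltage = 50, label = "rt")
  bin <- withr::local_tempfile(fileext = ".bin")
  write_trace(tr, bin, "binary")
  tr_bin <- read_trace(bin, "binary")
  expect_identical(tr_bin$samples, tr$samples)   # bit-exact
  expect_identical(tr_bin$sampling_interval, tr$sampling_interval)
  expect_identical(tr_bin$filter_cutoff, tr$filter_cutoff)
  expect_identical(tr_bin$voltage, tr$voltage)
  expect_identical(tr_bin$label, tr$label)

  tab <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, tab, "tabular")
  tr_tab <- read_trace(tab, "tabular")
  expect_equal(tr_tab$samples, tr$samples, tolerance = 1e-6)
  expect_identical(tr_tab$label, tr$label)
})

test_that("ABF reading degrades with a clear error", {
  expect_error(read_trace("whatever.abf", "abf"), "ABF")
})

test_that("event tables round trip on the fixed schema", {
  path <- withr::local_tempfile(fileext = ".csv")

  write_events(porepulse:::empty_events("x"), path)
  back <- read_events(path)
  expect_identical(nrow(back), 0L)
  expect_true(all(names(porepulse:::EVENT_SCHEMA) %in% names(back)))

  ev <- tibble::tibble(
    recording_id = c("a", "a", "b"),
    start_time = c(100, 5000, 260.5),
    dwell = c(1000, 250.25, 730),
    i_b = c(42.55, 50.1, 48.8),
    normalized_blockade = c(0.63, 0.55, 0.58),
    label = c("FPA", NA, "FPA-3")
  )
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(as.data.frame(back), as.data.frame(ev))

  broken <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("recording_id,start_time,i_b,normalized_blockade,label",
               "a,1,42,0.6,NA"), broken)
  expect_error(read_events(broken), "schema mismatch.*dwell")
})

test_that("pooling conserves event counts and per-recording features", {
  ev <- make_event_table(default_population_library()[2, ], 10)
  bl <- estimate_baseline(current_trace(rnorm(2000, 110, 1), 4))

  one <- concatenate_recordings(list(r1 = list(events = ev, baseline = bl)))
  expect_equal(one$normalized_blockade, ev$normalized_blockade)
  expect_equal(nrow(one), 10L)

  ev2 <- make_event_table(default_population_library()[2, ], 15, seed = 2)
  both <- concatenate_recordings(list(
    r1 = list(events = ev, baseline = bl),
    r2 = list(events = ev2, baseline = bl)
  ))
  expect_equal(nrow(both), 25L)
  expect_setequal(unique(both$recording_id), c("synthetic"))

  expect_error(
    concatenate_recordings(list(r1 = list(events = ev, baseline = NULL))),
    "lacks a baseline"
  )
  expect_error(
    concatenate_recordings(setNames(
      list(list(events = ev, baseline = bl),
           list(events = ev, baseline = bl)), c("r", "r"))),
    "unique"
  )
})

test_that("recordings with different open-pore currents pool unimodally", {
  # same true blockade fraction measured against two baselines: the
  # normalized blockades agree, so the pooled histogram carries one peak
  pop <- population_model("X", 0.55, 0.01, 2)
  make_rec <- function(i0, seed) {
    set.seed(seed)
    ev <- sample_population_events(pop, 1500)
    tibble::tibble(
      recording_id = sprintf("i0_%g", i0), start_time = NA_real_,
      dwell = ev$dwell, i_b = i0 * (1 - ev$blockade),
      normalized_blockade = (i0 - i0 * (1 - ev$blockade)) / i0,
      label = ev$name
    )
  }
  bl1 <- estimate_baseline(current_trace(rnorm(2000, 110, 1), 4))
  bl2 <- estimate_baseline(current_trace(rnorm(2000, 118, 1), 4))
  pooled <- concatenate_recordings(list(
    a = list(events = make_rec(110, 1), baseline = bl1),
    b = list(events = make_rec(118, 2), baseline = bl2)
  ))
  fit <- fit_gaussians(pooled$normalized_blockade, k = 1)
  expect_equal(fit$components$center, 0.55, tolerance = 0.005)
  # a single component captures essentially all pooled mass
  mass <- fit$components$amplitude * fit$components$width * sqrt(2 * pi) /
    diff(fit$histogram$bin_edges[1:2])
  expect_gt(mass / nrow(pooled), 0.95)
})
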