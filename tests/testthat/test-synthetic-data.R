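test_that("the default population library carries the measured signatures", {
  lib <- default_population_library()
  expect_equal(lib$blockade_mean[lib$name == "FPA"], 0.63)
  expect_equal(lib$blockade_sd[lib$name == "FPA-P1"], 0.02)
  expect_equal(lib$dwell_mode[lib$name == "FPA"], 5.74)
  expect_equal(lib$dwell_mode[lib$name == "FPA-6"], 0.95)
  expect_equal(lib$dwell_mode[lib$name == "FPA-P2"], 4.41)
  # blockade ordering in mixtures: FPA-P1 > FPA > FPA-P2 > FPA-3 > FPA-6
  expect_identical(lib$name[order(lib$blockade_mean, decreasing = TRUE)],
                   c("FPA-P1", "FPA", "FPA-P2", "FPA-3", "FPA-6"))
  expect_true(all(diff(lib$blockade_mean) < 0))
})

test_that("population models validate their parameter ranges", {
  expect_error(population_model("x", 1.2, 0.01, 1), "blockade_mean")
  expect_error(population_model("x", 0.5, 0, 1), "blockade_sd")
  expect_error(population_model("x", 0.5, 0.01, -1), "dwell_mode")
  expect_error(population_model("x", 0.5, 0.01, 1, rate = -2), "rate")
})

test_that("population sampling matches its generating distributions", {
  lib <- default_population_library()
  fpa <- lib[lib$name == "FPA", ]

  expect_identical(nrow(sample_population_events(fpa, 0)), 0L)

  set.seed(1)
  ev <- sample_population_events(fpa, 10000)
  # closed-form standard error oracle for the blockade mean
  expect_lt(abs(mean(ev$blockade) - 0.63), 3 * 0.01 / sqrt(10000))
  expect_equal(sd(ev$blockade), 0.01, tolerance = 0.05)

  # degenerate log-normal: all dwells sit exactly at the mode
  degen <- population_model("d", 0.5, 0.01, 2.5, dwell_sigma = 0)
  dd <- sample_population_events(degen, 1000)
  expect_true(all(dd$dwell == 2500))

  # log-normal mode parameterization: the empirical (kernel) mode of a
  # large sample sits within 5% of dwell_mode across the sigma range used.
  # The mode is read off a log-scale KDE (argmax of f_Y(y) * exp(-y) for
  # y = log dwell), with the analytic exp(bw^2) bandwidth-bias correction.
  for (sig in c(0.3, 0.6, 1.0)) {
    pop <- population_model("m", 0.5, 0.01, 2, dwell_sigma = sig)
    set.seed(7)
    d_ms <- sample_population_events(pop, 1e5)$dwell / 1000
    dens <- stats::density(log(d_ms), n = 4096, adjust = 2)
    g <- dens$y * exp(-dens$x)
    emp_mode <- exp(dens$x[which.max(g)] + dens$bw^2)
    expect_lt(abs(emp_mode - 2) / 2, 0.05)
  }
})

test_that("blockade truncation is invisible for the default populations", {
  # means sit tens of widths from (0, 1): the rejection step never fires,
  # so the draws are bit-identical to untruncated normals
  lib <- default_population_library()
  for (i in seq_len(nrow(lib))) {
    set.seed(11)
    got <- sample_population_events(lib[i, ], 5000)$blockade
    set.seed(11)
    invisible(rlnorm(5000, 1, lib$dwell_sigma[i]))  # same draw order
    want <- rnorm(5000, lib$blockade_mean[i], lib$blockade_sd[i])
    expect_identical(got, want)
    expect_lt(abs(mean(got) - lib$blockade_mean[i]), 1e-3)
  }
})

test_that("rendered traces carry the configured two-level structure", {
  pop <- population_model("X", 0.63, 0.01, 1)
  cfg <- simulation_config(pop, duration = 0.05, i0 = 115, noise_sd = 0,
                           filter_cutoff = NA, bumping = NULL, seed = 3)

  # single 1 ms event at blockade 0.63: interior samples at 115 * 0.37
  truth <- tibble::tibble(start_time = 20000, dwell = 1000, blockade = 0.63)
  tr <- render_trace(truth, cfg)
  idx <- (20000 / 4 + 2):((21000 / 4) - 1)
  expect_true(all(abs(tr$samples[idx] - 115 * (1 - 0.63)) < 1e-12))
  expect_equal(115 * (1 - 0.63), 42.55)

  # empty schedule: mean within 3 SE of i0
  cfg_noise <- simulation_config(pop, duration = 0.02, noise_sd = 1.7,
                                 filter_cutoff = NA, bumping = NULL, seed = 4)
  tr2 <- render_trace(truth[0, ], cfg_noise)
  n <- length(tr2$samples)
  expect_lt(abs(mean(tr2$samples) - 115), 3 * 1.7 / sqrt(n))

  expect_error(simulation_config(pop, duration = 0), "duration")
  overlapping <- tibble::tibble(start_time = c(0, 500), dwell = c(1000, 200),
                                blockade = 0.5)
  expect_error(render_trace(overlapping, cfg), "overlapping")
  past_end <- tibble::tibble(start_time = 49900, dwell = 1000, blockade = 0.5)
  expect_error(render_trace(past_end, cfg), "past the recording duration")
})

test_that("the low-pass filter has unity DC gain and the designed cutoff", {
  coef <- bessel_lowpass(5, 4)
  expect_equal(sum(coef$b) / sum(coef$a), 1, tolerance = 1e-12)

  set.seed(5)
  tr <- current_trace(rnorm(2e5, 115, 1.7), 4)
  filtered <- apply_lowpass(tr, 5)
  expect_equal(mean(filtered$samples), mean(tr$samples),
               tolerance = 1e-6 * mean(tr$samples))
  # white noise is attenuated to roughly sqrt(2 * ENBW / fs)
  expect_lt(sd(filtered$samples), 0.3 * sd(tr$samples))
  # -3 dB at the cutoff: a sinusoid at 5 kHz comes out at ~0.707 amplitude
  t_us <- (seq_len(5e4) - 1) * 4
  sine <- current_trace(sin(2 * pi * 5e3 * t_us * 1e-6), 4)
  out <- apply_lowpass(sine, 5)
  gain <- sd(out$samples[1e4:5e4]) / sd(sine$samples[1e4:5e4])
  expect_equal(gain, 1 / sqrt(2), tolerance = 0.02)
})

test_that("simulated recordings are reproducible and Poisson-consistent", {
  pop <- population_model("X", 0.5, 0.01, 1, rate = 20)
  cfg <- simulation_config(pop, duration = 2, bumping = NULL, seed = 99)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  # truth is sorted and non-overlapping
  expect_true(all(diff(a$truth$start_time) >= 0))
  expect_true(all(utils::head(a$truth$start_time + a$truth$dwell, -1) <=
                    utils::tail(a$truth$start_time, -1)))

  # Poisson oracle on the event count: rate 20/s for 100 s -> 2000 +/- 4*sqrt
  pop_fast <- population_model("X", 0.5, 0.01, 1, rate = 20)
  cfg_cnt <- simulation_config(pop_fast, duration = 100, bumping = NULL,
                               sampling_interval = 100, filter_cutoff = NA,
                               seed = 17)
  cnt <- nrow(simulate_recording(cfg_cnt)$truth)
  expect_lt(abs(cnt - 2000), 4 * sqrt(2000))
})

test_that("infeasible occupancy and bumping-only configs behave as specified", {
  dense <- population_model("X", 0.5, 0.01, 50, rate = 20)
  expect_error(simulation_config(dense, duration = 1, bumping = NULL) |>
                 simulate_recording(), "occupancy")

  cfg <- simulation_config(tibble::tibble(), duration = 5,
                           bumping = bumping_population(rate = 50), seed = 2)
  truth <- simulate_recording(cfg)$truth
  expect_true(all(truth$population == "bumping"))
  # log-normal mode 40 us, sigma 0.5: essentially all dwells under 200 us
  expect_gt(mean(truth$dwell < 200), 0.97)
})

test_that("simulation configs survive a YAML round trip", {
  cfg <- simulation_config(default_population_library()[1:2, ],
                           duration = 3.5, i0 = 118, seed = 12,
                           label = "yaml-rt")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  back <- read_simulation_config(path)
  expect_equal(back$i0, cfg$i0)
  expect_equal(back$duration, cfg$duration)
  expect_equal(as.data.frame(back$populations),
               as.data.frame(cfg$populations))
  expect_identical(back$seed, cfg$seed)
})
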