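#' Build a histogram for blockade levels or dwell times
#'
#' Blockade histograms use linear bins spanning \[0, 1\]; dwell histograms
#' use logarithmically spaced bins over the data range, matching how the
#' two axes are displayed and fitted.
#'
#' @param values Numeric vector (>= 1 value; dwell values must be > 0).
#' @param axis `"blockade"` or `"dwell"`.
#' @param n_bins Number of bins (defaults: 100 blockade, 50 dwell).
#' @return A `histogram_spec`: list with `bin_edges`, `counts`, `mids`,
#'   `axis`.
#' @export
build_histogram <- function(values, axis = c("blockade", "dwell"),
                            n_bins = NULL) {
  axis <- match.arg(axis)
  values <- values[is.finite(values)]
  if (length(values) == 0L) abort("empty input: nothing to histogram")
  if (is.null(n_bins)) n_bins <- if (axis == "blockade") 100L else 50L
  if (axis == "blockade") {
    edges <- seq(0, 1, length.out = n_bins + 1L)
  } else {
    if (any(values <= 0)) abort("dwell values must be > 0")
    lo <- min(values)
    hi <- max(values)
    if (lo == hi) {           # degenerate sample: one populated bin
      lo <- lo * 0.99
      hi <- hi * 1.01
    }
    edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1L))
    edges[[1L]] <- lo         # guard against rounding at the extremes
    edges[[n_bins + 1L]] <- hi
  }
  inside <- values >= edges[[1L]] & values <= edges[[length(edges)]]
  counts <- tabulate(
    pmin(findInterval(values[inside], edges, rightmost.closed = TRUE),
         n_bins),
    nbins = n_bins
  )
  structure(
    list(bin_edges = edges, counts = counts,
         mids = if (axis == "dwell") sqrt(edges[-1L] * edges[-length(edges)])
                else (edges[-1L] + edges[-length(edges)]) / 2,
         axis = axis),
    class = "histogram_spec"
  )
}

#' @export
print.histogram_spec <- function(x, ...) {
  cat(sprintf("<histogram (%s): %d bins, %d values>\n",
              x$axis, length(x$counts), sum(x$counts)))
  invisible(x)
}

# moving-average smoothing + local-maximum peak detection used to seed the
# Gaussian fits; peaks below `frac` of the global maximum are ignored
find_histogram_peaks <- function(counts, mids, smooth = 5L, frac = 0.05) {
  k <- rep(1 / smooth, smooth)
  s <- as.numeric(stats::filter(counts, k, sides = 2))
  s[is.na(s)] <- 0
  n <- length(s)
  if (n < 3L) return(integer())
  is_peak <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n],
               FALSE)
  is_peak <- is_peak & s > frac * max(s)
  # collapse plateaus of the smoothed curve to a single index
  idx <- which(is_peak)
  if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) > smooth)]
  idx
}

#' Fit a sum of Gaussian components to a blockade histogram
#'
#' Least-squares fit of `sum_j A_j * exp(-(x - c_j)^2 / (2 w_j^2))` to the
#' bin counts, mirroring the histogram-fitting workflow used to read
#' population centers off blockade-level distributions. When `init` is
#' absent, component centers are seeded from local maxima of the smoothed
#' histogram; an error is raised if fewer than `k` peaks are resolvable.
#'
#' @param values Numeric blockade levels, or a prebuilt `histogram_spec`.
#' @param k Number of components (>= 1).
#' @param init Optional numeric vector of `k` starting centers.
#' @param n_bins Bins used when `values` is raw data.
#' @return A `blockade_fit` with a `components` tibble (`amplitude`,
#'   `center`, `width`, sorted by center), `n_events`, `rss` and the
#'   histogram.
#' @examples
#' x <- rnorm(2000, 0.63, 0.01)
#' fit_gaussians(x, k = 1)
#' @export
fit_gaussians <- function(values, k = 1L, init = NULL, n_bins = 100L) {
  if (inherits(values, "histogram_spec")) {
    hist <- values
    n_events <- sum(hist$counts)
  } else {
    values <- values[is.finite(values)]
    if (length(values) > 0L && diff(range(values)) < 1e-12) {
      abort("degenerate input: all blockade values identical")
    }
    hist <- build_histogram(values, "blockade", n_bins)
    n_events <- length(values)
  }
  if (k < 1L) abort("k must be >= 1")
  nz <- sum(hist$counts > 0)
  if (nz < 3L * k + 1L) {
    abort(sprintf("too few populated bins (%d) to fit %d component(s)", nz, k))
  }
  mids <- hist$mids
  counts <- as.numeric(hist$counts)
  bw <- diff(hist$bin_edges[1:2])

  if (is.null(init)) {
    pk <- find_histogram_peaks(counts, mids)
    if (length(pk) < k) {
      abort(sprintf(
        "only %d peak(s) resolvable in the histogram but k = %d; supply init",
        length(pk), k))
    }
    pk <- pk[order(counts[pk], decreasing = TRUE)][seq_len(k)]
    centers0 <- sort(mids[pk])
  } else {
    if (length(init) != k) abort("init must supply one center per component")
    centers0 <- sort(as.double(init))
  }
  amp0 <- pmax(counts[vapply(centers0, function(cc) which.min(abs(mids - cc)),
                             integer(1))], 1)
  width0 <- rep(2 * bw, k)

  fit <- gaussian_ls_fit(mids, counts, amp0, centers0, width0, bw)
  comp <- fit$components[order(fit$components$center), ]
  structure(
    list(components = comp, n_events = n_events, rss = fit$rss, k = k,
         histogram = hist, converged = fit$converged),
    class = "blockade_fit"
  )
}

gaussian_ls_fit <- function(mids, counts, amp0, centers0, width0, bw) {
  k <- length(centers0)
  par0 <- c(amp0, centers0, width0)
  lower <- c(rep(0, k), rep(min(mids), k), rep(bw / 4, k))
  upper <- c(rep(max(counts) * 10 + 10, k), rep(max(mids), k), rep(0.25, k))
  model <- function(par) {
    a <- par[seq_len(k)]
    cc <- par[k + seq_len(k)]
    w <- par[2L * k + seq_len(k)]
    rowSums(vapply(seq_len(k), function(j) {
      a[[j]] * exp(-(mids - cc[[j]])^2 / (2 * w[[j]]^2))
    }, numeric(length(mids))))
  }
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = par0,
      fn = function(par) counts - model(par),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) abort(sprintf("Gaussian fit failed: %s", conditionMessage(e)))
  )
  if (res$info == 0) abort("Gaussian fit did not converge")
  par <- res$par
  list(
    components = tibble::tibble(
      component = seq_len(k),
      amplitude = par[seq_len(k)],
      center = par[k + seq_len(k)],
      width = abs(par[2L * k + seq_len(k)])
    ),
    rss = sum(res$fvec^2),
    converged = res$info %in% 1:4
  )
}

#' @export
print.blockade_fit <- function(x, ...) {
  cat(sprintf("<blockade_fit: %d component(s), n = %d>\n", x$k, x$n_events))
  print(x$components)
  invisible(x)
}

#' Fit a log-normal distribution to dwell times
#'
#' Default method is a least-squares fit of the expected bin occupancy of a
#' log-normal to the counts of a log-binned histogram (the same
#' histogram-led workflow as the blockade fits); `method = "mle"` uses the
#' closed-form maximum-likelihood estimates (moments of `log(x)`) and
#' serves as an independent cross-check. The most probable dwell is the
#' mode, `exp(mu - sigma^2)`.
#'
#' @param dwells Positive dwell times (any single unit; >= 50 values).
#' @param n_bins Histogram bins for the least-squares method.
#' @param method `"histogram"` (default) or `"mle"`.
#' @return A `dwell_fit`: list with `mu`, `sigma`, `mode`, `n_events`,
#'   `rss` (histogram method), `method`. `mode` is in the unit of `dwells`.
#' @export
fit_lognormal <- function(dwells, n_bins = 50L,
                          method = c("histogram", "mle")) {
  method <- match.arg(method)
  dwells <- dwells[is.finite(dwells)]
  if (any(dwells <= 0)) abort("non-positive dwell time")
  if (length(dwells) < 50L) abort("need at least 50 dwell values")
  lx <- log(dwells)
  mu_mle <- mean(lx)
  sd_mle <- sd(lx)
  if (sd_mle < 1e-9) {
    # degenerate sample: all dwells equal; mode is that value
    return(new_dwell_fit(mu_mle, 0, length(dwells), NA_real_, method))
  }
  if (method == "mle") {
    return(new_dwell_fit(mu_mle, sd_mle, length(dwells), NA_real_, "mle"))
  }
  hist <- build_histogram(dwells, "dwell", n_bins)
  counts <- as.numeric(hist$counts)
  edges <- hist$bin_edges
  model <- function(par) {
    # expected counts: n * (Phi(log upper) - Phi(log lower))
    p <- stats::pnorm(log(edges), par[[2L]], exp(par[[3L]]))
    par[[1L]] * diff(p)
  }
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = c(length(dwells), mu_mle, log(sd_mle)),
      fn = function(par) counts - model(par),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) abort(sprintf("log-normal fit failed: %s", conditionMessage(e)))
  )
  if (res$info == 0) abort("log-normal fit did not converge")
  new_dwell_fit(res$par[[2L]], exp(res$par[[3L]]), length(dwells),
                sum(res$fvec^2), "histogram")
}

new_dwell_fit <- function(mu, sigma, n, rss, method) {
  structure(
    list(mu = mu, sigma = sigma, mode = exp(mu - sigma^2),
         n_events = n, rss = rss, method = method),
    class = "dwell_fit"
  )
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("<dwell_fit (%s): mode = %.4g, mu = %.4g, sigma = %.4g, n = %d>\n",
              x$method, x$mode, x$mu, x$sigma, x$n_events))
  invisible(x)
}

#' Repeat a fit on bootstrap resamples to attach uncertainties
#'
#' Runs `fit_fun` on `n_repeats` seeded bootstrap resamples of `values`
#' (with replacement, full size) and reports the per-parameter mean and SD
#' across the repeats -- the package's reading of quoting parameter
#' uncertainties from a small number of independent fits. A failed resample
#' fit is retried with a fresh resample up to `retry_cap` times.
#'
#' @param values Numeric vector passed to `fit_fun`.
#' @param fit_fun Function of one numeric vector returning a fit object
#'   with a [tidy()] method (e.g. `\(x) fit_gaussians(x, k = 1)`).
#' @param n_repeats Number of bootstrap fits (default 3).
#' @param seed Optional integer seed for the resampling.
#' @param retry_cap Maximum retries per failed resample.
#' @return A `repeated_fit`: list with `base_fit` (fit on the full data),
#'   `params` (tibble: `term`, `mean`, `sd`), `n_repeats`.
#' @export
repeated_fit <- function(values, fit_fun, n_repeats = 3L, seed = NULL,
                         retry_cap = 5L) {
  base_fit <- fit_fun(values)
  if (!is.null(seed)) set.seed(seed)
  draws <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    fit_r <- NULL
    for (attempt in seq_len(retry_cap)) {
      resample <- sample(values, length(values), replace = TRUE)
      fit_r <- tryCatch(fit_fun(resample), error = function(e) NULL)
      if (!is.null(fit_r)) break
    }
    if (is.null(fit_r)) {
      abort(sprintf("bootstrap fit failed %d times in a row", retry_cap))
    }
    draws[[r]] <- tidy(fit_r)
  }
  params <- dplyr::bind_rows(draws) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      mean = mean(.data$estimate),
      sd = if (dplyr::n() > 1L) stats::sd(.data$estimate) else 0,
      .groups = "drop"
    )
  structure(
    list(base_fit = base_fit, params = params, n_repeats = n_repeats),
    class = "repeated_fit"
  )
}

#' @export
print.repeated_fit <- function(x, ...) {
  cat(sprintf("<repeated_fit: %d bootstrap repeat(s)>\n", x$n_repeats))
  print(x$params)
  invisible(x)
}

#' Select events inside a 2D box
#'
#' Retains events whose normalized blockade and dwell fall inside closed
#' intervals -- the box-selection step used to isolate one population of a
#' scatter plot before fitting its dwell distribution.
#'
#' @param events Event tibble.
#' @param blockade Length-2 numeric, blockade interval.
#' @param dwell_ms Length-2 numeric, dwell interval in ms.
#' @return The retained subset (a warning is raised when empty).
#' @export
select_box <- function(events, blockade = c(0, 1),
                       dwell_ms = c(0, Inf)) {
  events <- tibble::as_tibble(events)
  if (length(blockade) != 2L || length(dwell_ms) != 2L ||
      blockade[[1L]] > blockade[[2L]] || dwell_ms[[1L]] > dwell_ms[[2L]]) {
    abort("box intervals must be length-2 and non-empty")
  }
  d_ms <- events$dwell / US_PER_MS
  keep <- events$normalized_blockade >= blockade[[1L]] &
    events$normalized_blockade <= blockade[[2L]] &
    d_ms >= dwell_ms[[1L]] & d_ms <= dwell_ms[[2L]]
  out <- events[keep, ]
  if (nrow(out) == 0L) warn("box selection retained no events")
  out
}

#' Dual-parameter signature of one event population
#'
#' The pair (mean blockade level, most probable dwell time) that identifies
#' a peptide population, with bootstrap uncertainties: a single-Gaussian
#' fit on the blockade axis and a log-normal fit on dwell, each repeated on
#' resamples via [repeated_fit()].
#'
#' @param events Event tibble (>= 50 rows).
#' @param n_repeats Bootstrap repeats per fit.
#' @param seed Optional integer seed.
#' @param n_bins_blockade,n_bins_dwell Histogram bins for the two fits.
#' @return A one-row tibble: `blockade_mean`, `blockade_mean_sd`,
#'   `blockade_width`, `dwell_mode_ms`, `dwell_mode_sd_ms`, `dwell_sigma`,
#'   `n_events`.
#' @export
population_signature <- function(events, n_repeats = 3L, seed = NULL,
                                 n_bins_blockade = 100L, n_bins_dwell = 50L) {
  events <- tibble::as_tibble(events)
  if (nrow(events) < 50L) abort("need at least 50 events for a signature")
  seeds <- derive_seeds(seed, 2L)
  rb <- repeated_fit(events$normalized_blockade,
                     function(x) fit_gaussians(x, k = 1L,
                                               n_bins = n_bins_blockade),
                     n_repeats = n_repeats, seed = seeds[[1L]])
  rd <- repeated_fit(events$dwell / US_PER_MS,
                     function(x) fit_lognormal(x, n_bins = n_bins_dwell),
                     n_repeats = n_repeats, seed = seeds[[2L]])
  pb <- rb$params
  pd <- rd$params
  tibble::tibble(
    blockade_mean = rb$base_fit$components$center[[1L]],
    blockade_mean_sd = pb$sd[pb$term == "center_1"],
    blockade_width = rb$base_fit$components$width[[1L]],
    dwell_mode_ms = rd$base_fit$mode,
    dwell_mode_sd_ms = pd$sd[pd$term == "mode"],
    dwell_sigma = rd$base_fit$sigma,
    n_events = nrow(events)
  )
}

# deterministic sub-seeds below 2^31 derived from one integer (or NULL)
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L)
}
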