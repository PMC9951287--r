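#' Decompose a mixed-sample event set into population signatures
#'
#' The blockade axis leads: a `k`-component Gaussian fit to the blockade
#' histogram locates the populations, and each fitted component seeds a
#' selection box (center +/- 3 fitted widths, full dwell range) inside
#' which a log-normal dwell fit completes the dual-parameter signature.
#' Explicit `boxes` override the seeded ones. When the smoothed histogram
#' resolves fewer peaks than `k`, but more than one, the heaviest fitted
#' component is greedily split in two and the fit repeated until `k`
#' components stand (populations separated by less than a bin or two merge
#' under one histogram peak and need this); a single-peak histogram with
#' `k >= 2` is an error.
#'
#' Components whose center separation from a neighbour is less than twice
#' the pooled width are flagged `overlapping`: they are resolvable as
#' ensemble densities but single events cannot be attributed reliably.
#'
#' @param events Translocation-filtered event tibble.
#' @param k Number of populations (>= 1; `k = 1` is exactly
#'   [population_signature()]).
#' @param boxes Optional list of `k` lists with fields `blockade` and
#'   `dwell_ms` (length-2 intervals), as taken by [select_box()].
#' @param n_bins Blockade histogram bins.
#' @param n_repeats Bootstrap repeats for per-component uncertainties.
#' @param seed Optional integer seed for the bootstrap.
#' @return A `mixture_decomposition`: list with `signatures` (tibble sorted
#'   by descending blockade: `name`, `blockade_mean`, `blockade_sd`,
#'   `blockade_width`, `dwell_mode_ms`, `dwell_mode_sd_ms`, `dwell_sigma`,
#'   `weight`, `n_events`, `overlapping`), the `blockade_fit`, and the
#'   `boxes` used.
#' @export
decompose_mixture <- function(events, k, boxes = NULL, n_bins = 100L,
                              n_repeats = 3L, seed = NULL) {
  events <- tibble::as_tibble(events)
  if (k < 1L) abort("k must be >= 1")
  n_total <- nrow(events)
  if (n_total < 50L * k) {
    abort(sprintf("too few events (%d) to decompose into %d population(s)",
                  n_total, k))
  }

  if (k == 1L && is.null(boxes)) {
    sig <- population_signature(events, n_repeats = n_repeats, seed = seed)
    signatures <- tibble::tibble(
      name = "component_1",
      blockade_mean = sig$blockade_mean,
      blockade_sd = sig$blockade_mean_sd,
      blockade_width = sig$blockade_width,
      dwell_mode_ms = sig$dwell_mode_ms,
      dwell_mode_sd_ms = sig$dwell_mode_sd_ms,
      dwell_sigma = sig$dwell_sigma,
      weight = 1,
      n_events = sig$n_events,
      overlapping = FALSE
    )
    return(new_mixture_decomposition(signatures, NULL, NULL))
  }

  blockade <- events$normalized_blockade
  fit <- NULL
  if (is.null(boxes)) {
    hist <- build_histogram(blockade, "blockade", n_bins)
    pk <- find_histogram_peaks(as.numeric(hist$counts), hist$mids)
    if (length(pk) < k && length(pk) <= 1L) {
      abort(sprintf(
        "only %d peak(s) resolvable but k = %d; supply explicit boxes",
        length(pk), k))
    }
    p <- min(length(pk), k)
    ord <- pk[order(hist$counts[pk], decreasing = TRUE)][seq_len(p)]
    init <- sort(hist$mids[ord])
    fit <- fit_gaussians(blockade, k = p, init = init, n_bins = n_bins)
    # fewer resolvable peaks than k: populations merged under one peak are
    # teased apart by greedily splitting the heaviest fitted component in
    # two and refitting, until k components stand; several split offsets
    # are tried and the lowest-residual fit kept (the split of two
    # components a bin or two apart is weakly identified, so a single
    # starting point can settle in a local optimum)
    while (fit$k < k) {
      comp <- fit$components
      mass <- comp$amplitude * comp$width
      j <- which.max(mass)
      bw <- diff(fit$histogram$bin_edges[1:2])
      best <- NULL
      for (off_scale in c(0.35, 0.5, 0.75, 1)) {
        off <- max(comp$width[[j]] * off_scale, bw / 2)
        init <- sort(c(comp$center[-j],
                       comp$center[[j]] - off, comp$center[[j]] + off))
        cand <- tryCatch(
          fit_gaussians(blockade, k = fit$k + 1L, init = init,
                        n_bins = n_bins),
          error = function(e) NULL)
        if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) {
          best <- cand
        }
      }
      if (is.null(best)) {
        abort(sprintf("could not split a merged component toward k = %d", k))
      }
      fit <- best
    }
    boxes <- purrr::map(seq_len(k), function(j) {
      list(
        blockade = c(fit$components$center[[j]] - 3 * fit$components$width[[j]],
                     fit$components$center[[j]] + 3 * fit$components$width[[j]]),
        dwell_ms = c(0, Inf)
      )
    })
  } else {
    if (length(boxes) != k) abort("boxes must supply one box per component")
  }

  # weight = fraction of translocations under each fitted Gaussian (the
  # component mass, integral A * w * sqrt(2*pi), in events); with explicit
  # boxes it falls back to the box occupancy. Non-Gaussian background mass
  # stays unassigned, so the weights can sum to less than one.
  gauss_weight <- function(j) {
    bw <- diff(fit$histogram$bin_edges[1:2])
    min(1, fit$components$amplitude[[j]] * fit$components$width[[j]] *
          sqrt(2 * pi) / bw / n_total)
  }

  seeds <- derive_seeds(seed, length(boxes))
  rows <- purrr::imap(boxes, function(bx, j) {
    sub <- suppressWarnings(
      select_box(events, blockade = bx$blockade, dwell_ms = bx$dwell_ms)
    )
    if (nrow(sub) < 50L) {
      abort(sprintf("component %d box holds %d events (< 50); cannot fit dwell",
                    j, nrow(sub)))
    }
    sig <- population_signature(sub, n_repeats = n_repeats, seed = seeds[[j]])
    tibble::tibble(
      name = sprintf("component_%d", j),
      blockade_mean = if (is.null(fit)) sig$blockade_mean
                      else fit$components$center[[j]],
      blockade_sd = sig$blockade_mean_sd,
      blockade_width = if (is.null(fit)) sig$blockade_width
                       else fit$components$width[[j]],
      dwell_mode_ms = sig$dwell_mode_ms,
      dwell_mode_sd_ms = sig$dwell_mode_sd_ms,
      dwell_sigma = sig$dwell_sigma,
      weight = if (is.null(fit)) nrow(sub) / n_total else gauss_weight(j),
      n_events = nrow(sub),
      overlapping = FALSE
    )
  })
  signatures <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$blockade_mean))
  signatures$name <- sprintf("component_%d", seq_len(nrow(signatures)))
  signatures$overlapping <- flag_overlaps(signatures$blockade_mean,
                                          signatures$blockade_width)
  new_mixture_decomposition(signatures, fit, boxes)
}

# separation below 2x pooled width means single events are ambiguous
flag_overlaps <- function(centers, widths) {
  n <- length(centers)
  if (n < 2L) return(rep(FALSE, n))
  flag <- rep(FALSE, n)
  for (j in seq_len(n - 1L)) {
    sep <- abs(centers[[j]] - centers[[j + 1L]])
    pooled <- sqrt((widths[[j]]^2 + widths[[j + 1L]]^2) / 2)
    if (sep < 2 * pooled) flag[c(j, j + 1L)] <- TRUE
  }
  flag
}

new_mixture_decomposition <- function(signatures, fit, boxes) {
  structure(
    list(signatures = signatures, blockade_fit = fit, boxes = boxes),
    class = "mixture_decomposition"
  )
}

#' @export
print.mixture_decomposition <- function(x, ...) {
  cat(sprintf("<mixture_decomposition: %d population(s)>\n",
              nrow(x$signatures)))
  print(x$signatures)
  invisible(x)
}

#' Assign individual events to decomposed populations
#'
#' Each event is scored against every signature by a standardized 2D
#' distance, `sqrt(((b - center)/width)^2 + ((log d - log mode)/sigma)^2)`,
#' and assigned to the nearest component; events farther than `cutoff`
#' standardized units from every component are labeled `"unassigned"`.
#' Exact ties break toward the higher-blockade component.
#'
#' @param events Event tibble.
#' @param decomposition A `mixture_decomposition`.
#' @param cutoff Maximum standardized distance (default 4).
#' @return `events` with columns `label` (component name) and `score` (the
#'   standardized distance to the assigned component).
#' @export
assign_events <- function(events, decomposition, cutoff = 4) {
  if (!inherits(decomposition, "mixture_decomposition")) {
    abort("decomposition must be a mixture_decomposition")
  }
  events <- tibble::as_tibble(events)
  sig <- decomposition$signatures   # sorted by descending blockade
  if (nrow(events) == 0L) {
    events$label <- character()
    events$score <- double()
    return(events)
  }
  d_ms <- events$dwell / US_PER_MS
  dist <- vapply(seq_len(nrow(sig)), function(j) {
    sqrt(((events$normalized_blockade - sig$blockade_mean[[j]]) /
            sig$blockade_width[[j]])^2 +
         ((log(d_ms) - log(sig$dwell_mode_ms[[j]])) /
            max(sig$dwell_sigma[[j]], 1e-6))^2)
  }, numeric(nrow(events)))
  dist <- matrix(dist, nrow = nrow(events))
  # which.min on each row returns the first (= highest-blockade) component
  # among exact ties, implementing the documented tie rule
  best <- apply(dist, 1L, which.min)
  score <- dist[cbind(seq_len(nrow(events)), best)]
  label <- sig$name[best]
  label[score > cutoff] <- "unassigned"
  events$label <- label
  events$score <- score
  events
}

#' Score an assignment against ground truth
#'
#' @param labels Character vector of assigned labels (may include
#'   `"unassigned"`).
#' @param ground_truth Character vector of true population names, same
#'   length.
#' @param classes Optional character vector fixing the label universe;
#'   labels outside it (other than `"unassigned"`) are an error.
#' @return A list with `confusion` (truth in rows, assignment in columns),
#'   `recall` (named per true class), `accuracy`, `n`.
#' @export
evaluate_assignment <- function(labels, ground_truth, classes = NULL) {
  if (length(labels) != length(ground_truth)) {
    abort("labels and ground_truth lengths differ")
  }
  if (anyNA(labels) || anyNA(ground_truth)) abort("unknown label: NA present")
  if (is.null(classes)) classes <- sort(unique(ground_truth))
  stray <- setdiff(unique(labels), c(classes, "unassigned"))
  stray_truth <- setdiff(unique(ground_truth), classes)
  if (length(stray_truth) > 0L) {
    abort(sprintf("unknown label in ground truth: %s", stray_truth[[1L]]))
  }
  if (length(stray) > 0L) {
    abort(sprintf("unknown label in assignment: %s", stray[[1L]]))
  }
  lv_pred <- c(classes, "unassigned")
  confusion <- table(
    truth = factor(ground_truth, levels = classes),
    assigned = factor(labels, levels = lv_pred)
  )
  correct <- labels == ground_truth
  recall <- vapply(classes, function(cl) {
    idx <- ground_truth == cl
    if (!any(idx)) return(NA_real_)
    mean(correct[idx])
  }, numeric(1))
  list(
    confusion = confusion,
    recall = recall,
    accuracy = mean(correct),
    n = length(labels)
  )
}
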