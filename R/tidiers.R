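#' Tidy a blockade fit
#'
#' One row per fitted parameter, broom style: `amplitude_j`, `center_j`,
#' `width_j` for each component `j` in ascending-center order.
#'
#' @param x A `blockade_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`.
#' @method tidy blockade_fit
#' @export
tidy.blockade_fit <- function(x, ...) {
  comp <- x$components
  tibble::tibble(
    term = c(sprintf("amplitude_%d", comp$component),
             sprintf("center_%d", comp$component),
             sprintf("width_%d", comp$component)),
    estimate = c(comp$amplitude, comp$center, comp$width)
  )
}

#' @rdname tidy.blockade_fit
#' @method glance blockade_fit
#' @export
glance.blockade_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n_events = x$n_events, rss = x$rss,
                 converged = x$converged)
}

#' Tidy a dwell-time fit
#'
#' @param x A `dwell_fit`.
#' @param ... Unused.
#' @return A tibble with `term` (`mu`, `sigma`, `mode`) and `estimate`.
#' @method tidy dwell_fit
#' @export
tidy.dwell_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma", "mode"),
                 estimate = c(x$mu, x$sigma, x$mode))
}

#' @rdname tidy.dwell_fit
#' @method glance dwell_fit
#' @export
glance.dwell_fit <- function(x, ...) {
  tibble::tibble(method = x$method, n_events = x$n_events, rss = x$rss)
}

#' Tidy a repeated (bootstrap) fit
#'
#' @param x A `repeated_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `mean`, `sd` across bootstrap repeats.
#' @method tidy repeated_fit
#' @export
tidy.repeated_fit <- function(x, ...) x$params

#' Tidy a mixture decomposition
#'
#' @param x A `mixture_decomposition`.
#' @param ... Unused.
#' @return The signature tibble, sorted by descending blockade mean.
#' @method tidy mixture_decomposition
#' @export
tidy.mixture_decomposition <- function(x, ...) x$signatures

#' @rdname tidy.mixture_decomposition
#' @method glance mixture_decomposition
#' @export
glance.mixture_decomposition <- function(x, ...) {
  tibble::tibble(
    k = nrow(x$signatures),
    n_events = sum(x$signatures$n_events),
    any_overlapping = any(x$signatures$overlapping)
  )
}
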