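#' Construct a peptide population model
#'
#' A population model is the generative signature of one peptide species (or
#' one conformation): a Gaussian normalized-blockade level, a log-normal
#' dwell time parameterized by its most probable value (the mode), and a
#' Poisson arrival rate. The log-normal convention used throughout the
#' package is `mode = exp(mu - sigma^2)`, i.e. `mu = log(mode) + sigma^2`.
#'
#' @param name Population name.
#' @param blockade_mean Mean normalized blockade level, strictly in (0, 1).
#' @param blockade_sd Gaussian width of the blockade level, > 0.
#' @param dwell_mode Most probable dwell time in ms, > 0.
#' @param dwell_sigma Log-normal shape parameter (dimensionless, >= 0).
#' @param rate Expected arrival rate in events per second, >= 0.
#' @param peptide_length Residue count (metadata).
#' @param net_charge Net charge in elementary units (metadata).
#'
#' @return A one-row tibble; population libraries are formed by row-binding.
#' @export
population_model <- function(name, blockade_mean, blockade_sd, dwell_mode,
                             dwell_sigma = 0.6, rate = 20,
                             peptide_length = NA_integer_,
                             net_charge = NA_real_) {
  if (!(blockade_mean > 0 && blockade_mean < 1)) {
    abort("blockade_mean must lie strictly in (0, 1)")
  }
  if (blockade_sd <= 0) abort("blockade_sd must be > 0")
  if (dwell_mode <= 0) abort("dwell_mode must be > 0 (ms)")
  if (dwell_sigma < 0) abort("dwell_sigma must be >= 0")
  if (rate < 0) abort("rate must be >= 0")
  tibble::tibble(
    name = as.character(name),
    blockade_mean = blockade_mean,
    blockade_sd = blockade_sd,
    dwell_mode = dwell_mode,
    dwell_sigma = dwell_sigma,
    rate = rate,
    peptide_length = as.integer(peptide_length),
    net_charge = net_charge
  )
}

#' Default fibrinopeptide A population library
#'
#' The five populations observed for the fibrinopeptide A family through a
#' wild-type aerolysin pore at +50 mV in 4 M KCl: unmodified FPA (16
#' residues), the two conformations of Ser3-phosphorylated FPA (FPA-P1,
#' FPA-P2), and the N-terminally truncated derivatives FPA-3 (13 residues)
#' and FPA-6 (10 residues). Blockade means/widths and most probable dwell
#' times are the ensemble values measured for the individual peptides; the
#' log-normal shape and the arrival rate are simulation defaults and can be
#' overridden per population.
#'
#' @param dwell_sigma Log-normal shape applied to every population.
#' @param rate Arrival rate (events/s) applied to every population.
#' @return A five-row population tibble ordered by decreasing blockade:
#'   FPA-P1 > FPA > FPA-P2 > FPA-3 > FPA-6.
#' @examples
#' default_population_library()
#' @export
default_population_library <- function(dwell_sigma = 0.6, rate = 20) {
  dplyr::bind_rows(
    population_model("FPA-P1", 0.71, 0.02, 0.62, dwell_sigma, rate, 16L, -5),
    population_model("FPA",    0.63, 0.01, 5.74, dwell_sigma, rate, 16L, -3),
    population_model("FPA-P2", 0.61, 0.01, 4.41, dwell_sigma, rate, 16L, -5),
    population_model("FPA-3",  0.55, 0.01, 2.50, dwell_sigma, rate, 13L, NA),
    population_model("FPA-6",  0.43, 0.01, 0.95, dwell_sigma, rate, 10L, NA)
  )
}

#' Default bumping population
#'
#' Brief, shallow current deviations from molecules that approach the pore
#' mouth without entering: dwell well under 200 us and a low blockade level.
#' Used by the simulator so that the short-event cluster removed by
#' [filter_translocations()] is present in synthetic recordings.
#'
#' @param rate Arrival rate in events/s.
#' @return A one-row population tibble named `"bumping"`.
#' @export
bumping_population <- function(rate = 20) {
  population_model("bumping", 0.25, 0.08, 0.040, 0.5, rate)
}

#' Sample per-event parameters from one population
#'
#' Dwell times are log-normal with the population's most probable value,
#' `mode = exp(mu - sigma^2)`; blockade levels are Gaussian truncated to
#' (0, 1) by rejection (for the default populations the bounds are tens of
#' widths away, so truncation is numerically invisible).
#'
#' @param pop A one-row population tibble (see [population_model()]).
#' @param n Number of events to draw (>= 0).
#' @return A tibble with columns `dwell` (us), `blockade`, `name`.
#' @export
sample_population_events <- function(pop, n) {
  pop <- validate_population(pop)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) abort("n must be a non-negative count")
  if (n == 0L) {
    return(tibble::tibble(dwell = double(), blockade = double(),
                          name = character()))
  }
  mu <- log(pop$dwell_mode) + pop$dwell_sigma^2
  dwell_ms <- if (pop$dwell_sigma == 0) rep(pop$dwell_mode, n) else
    rlnorm(n, meanlog = mu, sdlog = pop$dwell_sigma)
  blockade <- rnorm(n, pop$blockade_mean, pop$blockade_sd)
  out <- which(blockade <= 0 | blockade >= 1)
  while (length(out) > 0L) {
    blockade[out] <- rnorm(length(out), pop$blockade_mean, pop$blockade_sd)
    out <- out[blockade[out] <= 0 | blockade[out] >= 1]
  }
  tibble::tibble(dwell = dwell_ms * US_PER_MS, blockade = blockade,
                 name = pop$name)
}

validate_population <- function(pop) {
  pop <- tibble::as_tibble(pop)
  if (nrow(pop) != 1L) abort("expected a single population (one row)")
  needed <- c("name", "blockade_mean", "blockade_sd", "dwell_mode",
              "dwell_sigma", "rate")
  missing_cols <- setdiff(needed, names(pop))
  if (length(missing_cols) > 0L) {
    abort(sprintf("population lacks field(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!(pop$blockade_mean > 0 && pop$blockade_mean < 1) ||
      pop$blockade_sd <= 0 || pop$dwell_mode <= 0 || pop$dwell_sigma < 0 ||
      pop$rate < 0) {
    abort(sprintf("invalid population model '%s'", pop$name))
  }
  pop
}
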