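---
title: "Resistive-pulse peptide discrimination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resistive-pulse peptide discrimination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porepulse)
```

## The measurement this package models

A biological nanopore (wild-type aerolysin here) inserted in a lipid
membrane passes a steady ionic current $I_0$ under constant voltage.
When a peptide enters the pore the current drops to a blockade level
$I_b$ for the time the molecule resides there. Each such event yields two
electrical parameters:

* the **normalized blockade level** $(I_0 - I_b)/I_0$, which reports the
  fraction of the pore cross-section the analyte occludes and depends on
  peptide size and conformation, and
* the **dwell time**, the residence time of the molecule in the pore.

Across thousands of events a peptide species forms a population in the
(blockade, dwell) plane. Its ensemble signature is the pair (Gaussian
center of the blockade histogram, mode of the log-normal dwell
distribution). The package was built around the fibrinopeptide A (FPA)
family: FPA itself, the two conformations of its Ser3-phosphorylated form
(FPA-P1 helical-like, FPA-P2 extended), and the N-terminally truncated
derivatives FPA-3 and FPA-6. Their default parameters, as measured through
aerolysin at +50 mV in 4 M KCl, are in
`default_population_library()`:

```{r}
default_population_library()
```

Blockade means are strictly ordered FPA-P1 > FPA > FPA-P2 > FPA-3 > FPA-6,
which is what makes single-recording mixture discrimination possible, and
the FPA/FPA-P2 pair (0.63 vs 0.61) is the deliberately hard case: two
populations closer than three histogram bins.

## The synthetic-recording generator

`simulate_recording()` produces a current trace plus per-event ground
truth. It emulates the features of a real acquisition that the analysis
depends on, and only those:

* **Baseline**: samples are $\mathcal N(I_0, \sigma_\text{noise})$ with
  defaults $I_0 = 115$ pA and $\sigma_\text{noise} = 1.7$ pA, matching the
  open-pore levels and printed spreads of typical recordings.
* **Events**: rectangular two-level excursions to $I_0(1-b)$. The analysis
  extracts only one mean blockade per event, so intra-event structure
  beyond additive noise is not modeled.
* **Arrivals**: per population the event count is Poisson with mean
  rate × duration; start times are uniform with overlap rejection and
  redraw, which preserves the expected counts. An expected pore occupancy
  above 0.5 is refused rather than silently serialized.
* **Dwell times**: log-normal, parameterized by the most probable value
  (the mode), with $\mu = \log(\text{mode}) + \sigma^2$. The shape
  $\sigma$ is not printed for the measured populations; the default 0.6
  reproduces the visually single-decade-wide dwell histograms of real
  recordings and is exposed per population.
* **Blockades**: Gaussian truncated to (0, 1). For all default populations
  the bounds lie tens of widths away, so truncation never fires in
  practice.
* **Bumping events**: molecules that touch the pore mouth without
  entering produce brief, shallow blockades. The default bumping
  population (log-normal mode 40 µs, $\sigma = 0.5$; blockade
  0.25 ± 0.08; rate equal to the summed translocation rate) qualitatively
  reproduces that short/low cluster so the 200 µs translocation filter has
  something real to remove.
* **Filtering**: a digital 4-pole Bessel low-pass at 5 kHz — the standard
  anti-aliasing filter of patch-clamp amplifiers — applied to the
  assembled trace sampled at 4 µs (250 kHz). The filter is built from the
  magnitude-normalized analog prototype poles by bilinear transform with
  cutoff prewarping and normalized to exactly unity DC gain; its 10–90%
  step rise time at 5 kHz is ≈ 70 µs. Filtering is one-pass (causal), as
  in the instrument it mimics: the constant group delay shifts every
  feature equally and cancels out of dwell measurements.

Everything is reproducible from one integer seed with a documented draw
order (counts, per-population event parameters, placement, noise).

What the generator does **not** emulate: 1/f noise, baseline drift,
capacitive transients, voltage- or charge-dependent capture rates,
intra-event sub-states, and any concentration–rate calibration (mixture
rates default to equal and are set explicitly otherwise). Tests passing
on these simulations therefore demonstrate that the estimators are
unbiased and stable under the stated statistical model, not that the
pipeline is robust to instrument pathologies outside it.

## Baseline estimation and event detection

The open-pore level is estimated per recording and frozen before
detection. `estimate_baseline()` iterates: compute mean and SD over
retained samples, exclude samples below mean − 5·SD, repeat to
convergence. The iteration is seeded with the median and scaled MAD
rather than the raw mean/SD: with tens of percent of samples inside deep
blockades the raw moments are so inflated that the exclusion threshold
falls below every event sample and nothing would ever be excluded,
whereas the median of a trace less than half-blocked sits on the
baseline. Only the downward tail is excluded because analytes reduce the
current at this polarity.

`detect_events()` implements the threshold rule: an event is each maximal
run of at least 2 consecutive samples below $I_0 - 5\delta$, with
$\delta$ the baseline SD of the recorded (filtered) trace. Boundaries sit
at the first and last sub-threshold samples; events touching the trace
ends are discarded (their dwell is unknowable); upward excursions are
ignored. The 2-sample minimum (8 µs at 4 µs sampling) discards
single-sample noise spikes.

Two measurement corrections matter on filtered traces, and both are
driven by the same number — the filter step response:

* **Blockade level.** The threshold crossing sits only ~12% down the
  filtered falling edge, so the first/last event samples lie on the
  settling flanks. The interior mean therefore excludes, besides the
  boundary samples, an `edge_exclude` guard per side (default: the
  settle-past-threshold time, ≈ 550 µs·kHz / cutoff, i.e. 28 samples at
  5 kHz; 0 for unfiltered traces; the guard shrinks for short events).
  With the guard the interior is pure plateau and the recovered blockade
  mean is unbiased to < 0.005 for every default population.
* **Dwell time.** The entry crossing sits ~12% down the falling edge but
  the exit crossing ~88% up the rising edge, so threshold-to-threshold
  dwell is systematically stretched by ≈ 66 µs at 5 kHz — negligible for
  FPA (5.74 ms) but ~11% of the FPA-P1 mode (0.62 ms).
  `refine_midpoint = TRUE` re-times each boundary at the 50%-amplitude
  crossing of that event's own depth (with sub-sample interpolation),
  which is symmetric on both edges and cancels the broadening.
  `detect_events()` keeps the literal threshold rule as its default;
  `pipeline_config()` switches the refinement on because every filtered
  analysis should want it.

`filter_translocations()` then separates translocation/interaction events
(dwell > 200 µs) from the bumping cluster.

## Distribution fitting

Population parameters are read off histograms, mirroring the
histogram-led workflow used in practice:

* **Blockade**: 100 linear bins on [0, 1] (resolving 0.01-scale
  separations); `fit_gaussians()` least-squares fits a sum of $k$
  Gaussians to the counts with `minpack.lm`, seeded from local maxima of
  a 5-bin moving-average smoothed histogram (peaks below 5% of the global
  maximum ignored). Centers are returned sorted; asking for more
  components than resolvable peaks without explicit starting centers is
  an error rather than a silent overfit.
* **Dwell**: 50 log-spaced bins; `fit_lognormal()` fits the expected bin
  occupancy of a log-normal to the counts and reports
  $\mu$, $\sigma$ and the mode $e^{\mu - \sigma^2}$ (the identity holds
  exactly on the returned parameters). The closed-form MLE (moments of
  $\log x$) is available as `method = "mle"` and serves as an independent
  cross-check; the two agree within 5% on clean samples.
* **Uncertainties**: quoted parameter spreads come from a small number of
  independent fits. With a single recording the package realizes this as
  `repeated_fit()`: seeded bootstrap resamples (full size, with
  replacement), default 3, reporting per-parameter mean ± SD. These SDs
  are honest resampling spreads — of order 10⁻³ for a blockade center at
  n ≈ 3000 — and are intentionally not inflated to match any printed
  ± values, which reflect between-fit and between-recording variation.

## Mixture decomposition and event assignment

`decompose_mixture()` lets the blockade axis lead, because that is where
the populations separate: a $k$-component Gaussian fit locates the
centers, each component seeds a selection box (center ± 3 fitted widths,
all dwells), and a log-normal dwell fit inside each box completes the
(blockade, dwell-mode) signature. Component weights are the fitted
Gaussian masses, so overlapping boxes cannot double-count and
non-Gaussian background stays unassigned.

When populations sit closer than the histogram can resolve as separate
peaks — FPA and FPA-P2 merge under one peak at any realistic n — the
decomposition first fits the resolvable peaks, then greedily splits the
heaviest component in two and refits, trying several split offsets
(0.35–1 × width) and keeping the lowest-residual fit, until $k$
components stand. The multi-start matters: the split of two components
two bins apart is weakly identified and a single starting point can
settle in a local optimum several thousandths off. A single-peak
histogram with $k \ge 2$ is refused. Components whose separation is
below twice the pooled width are flagged `overlapping` in reports:
their ensemble centers are trustworthy, individual events are not
attributable between them.

`assign_events()` scores each event against each signature with the
standardized distance
$\sqrt{((b - c)/w)^2 + ((\log d - \log m)/\sigma)^2}$
and assigns the nearest component; events farther than 4 standardized
units from everything are `"unassigned"` (keeping bumping-tail
contamination out of population statistics), and exact ties break toward
the higher-blockade component. Event-level accuracy numbers are
properties of this artifact, not ensemble claims: with the default
five populations, accuracy is ≥ 90% away from the FPA/FPA-P2 pair and
≥ 75% overall, and it degrades monotonically as blockade separations
shrink.

## Numerical and design choices

| Parameter | Default | Units | Why |
|---|---|---|---|
| `i0` | 115 | pA | typical open-pore level at +50 mV |
| `noise_sd` | 1.7 | pA | matches printed open-pore spreads (pre-filter) |
| `sampling_interval` | 4 | µs | 250 kHz acquisition |
| `filter_cutoff` | 5 | kHz | 4-pole Bessel, amplifier standard |
| `k` (threshold) | 5 | δ | the printed detection rule |
| `min_samples` | 2 | samples | 8 µs floor; single-sample spikes are noise |
| `min_dwell` | 200 | µs | bumping/translocation boundary |
| `dwell_sigma` | 0.6 | — | single-decade dwell histograms |
| `edge_exclude` | 550/cutoff | µs | filter settle past threshold |
| blockade bins | 100 on [0,1] | — | resolves 0.01-scale separations |
| dwell bins | 50, log | — | decade-spanning dwell range |
| `n_repeats` | 3 | — | independent-fit convention |
| assignment cutoff | 4 | std. units | excludes stray/bumping tails |

Degenerate inputs are handled explicitly: constant traces give
$\delta = 0$ (legal; the threshold rule still works on noiseless
synthetic data), an all-equal dwell sample returns its common value as
the mode instead of a failed fit, all-identical blockades are a
degenerate-width error, and empty box selections warn rather than fail.

Rates and recording durations are engineering choices, not measured
claims: nothing in the source recordings pins them down. Defaults use
20 events/s per population; the five-population mixture runs at
12 events/s per population purely to keep expected pore occupancy near
0.3 (five populations at 20/s with these dwell modes would sit at the
0.5 feasibility edge of non-overlapping placement). Whether the two
FPA-P conformations interconvert within a recording is unknowable from
ensemble data; they are simulated as independent populations.

The end-to-end recovery checks (and `scripts/acceptance.R`) use
recordings of 100–170 s at these rates — 25–43 M samples, ≥ 3000
translocations per single-peptide recording and ≥ 10000 for the
five-population mixture — sizes chosen so that the sampling error of a
fitted center (~2·10⁻⁴) is well below the 0.01 tolerances being
verified, while a full check runs in tens of seconds on one CPU.

## Known limitations

* The dwell axis is corrected for filter broadening only via midpoint
  refinement; no deconvolution of the dwell distribution is attempted,
  and events shorter than the filter rise time are attenuated rather
  than recovered (they fall in the bumping bin by construction).
* The 200 µs translocation filter truncates the lowest ~0.7% of the
  FPA-P1 dwell distribution, nudging its fitted mode up by a few
  percent; this is visible in end-to-end runs and left uncorrected.
* Baseline drift and adaptive baseline tracking are out of scope; the
  baseline is frozen per recording.
* Component identifiability relies on sorted centers only; no label
  switching correction beyond sorting is applied across bootstrap
  repeats of multi-component fits (signatures are refit per box, which
  sidesteps most of it).
* ABF files are not parsed; recordings arrive as the package's tabular
  or binary containers, or as pre-extracted event tables.
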