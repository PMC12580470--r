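---
title: "Methods: temporal displacement from paired camera-trap surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal displacement from paired camera-trap surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielshift)
```

This vignette documents the statistical procedures in `dielshift`, the
assumptions behind them, the defaults and why they were chosen, and what
the synthetic-data generator does and does not emulate.

## The study design being modelled

The design is a paired trail/forest camera-trap survey in a protected
area where hunting is confined to a border zone and varies strongly over
the year, while recreation (hiking, biking) happens mostly on trails and
during the day. Each *location* contributes a camera on a trail and a
paired camera 100 m away in the forest. Disturbance enters the analysis
through four axes: hunting-effort stratum (time), camera placement
(trail vs forest), recreation intensity at the location's trail, and
hunting-zone membership / distance to the zone border (space).

## Independent events

Camera triggers are collapsed into independent events per camera ×
class. A record belongs to the current event if its gap to the
*immediately preceding* record is below the threshold; a gap at or above
the threshold opens a new event (record-to-record chaining, the dominant
camera-trap convention — a queue of hikers passing for a minute counts
once even though the first and last trigger are far apart). Thresholds:
8 s for humans, 300 s for wildlife. The filter is idempotent, and the
test suite verifies equivalence against a brute-force scan on random
streams. Group size is deliberately ignored: one sounder of boar counts
the same as one boar.

## Effort strata

Each study month is classed by its share of all successful hunting
events over the study window: below 5% low, 5–10% (inclusive at both
ends) medium, above 10% high. Contiguous months form *windows*; with a
study spanning 13 months the high stratum occurs as two windows at the
turns of the year, which are pooled for all event-level analyses but
kept separate where the procedure is explicitly per-window (the
recreation median split, below). Trap days are whole calendar days on
which a camera was deployed and not excluded (outages, lens obstruction);
partial first/last days count as active.

## RAI, trail index, and the location bootstrap

The relative abundance index is `100 * events / trap-days`, an index of
use intensity, not density. The trail index
`ln((RAI_trail + 1)/(RAI_forest + 1))` compares placements on a log
scale; the `+1` keeps zero-RAI cells finite and makes the index
antisymmetric under swapping placements. The natural log is used: it
reproduces the published worked values at two decimals while log10 does
not.

Uncertainty is a nonparametric bootstrap over *locations*: a resampled
location contributes both its cameras, so trail and forest estimates in
one replicate come from the same location draw and every
trail-vs-forest or cross-stratum contrast is paired. All strata and
placements are computed inside a single statistic per replicate for the
same reason. Intervals are 2.5/97.5 percentile; replicates where a
statistic is undefined (for instance all resampled trap days zero) are
dropped and counted. A contrast is flagged significant when its CI
excludes zero. Coverage of the pooled-RAI interval is checked by
simulation (200 synthetic datasets at the study's 61 locations; the 95%
CI must cover truth 90–99% of the time).

## Solar time and day/night

Sun position uses the NOAA low-accuracy ephemeris (fractional-year
expansions of solar declination and the equation of time), accurate to
a few hundredths of a degree — far better than needed to place twilight
to the minute. Rise/set uses the −0.833° refraction convention; night is
the half-open interval from evening nautical-twilight onset (−12°,
descending) to morning nautical-twilight end (−12°, ascending), with
dawn-end classed as day and dusk-start as night.

Clock time is mapped to *solar radians* with a date-specific
double-anchored transform: `[sunrise, sunset] -> [π/2, 3π/2]` linearly,
and the night stretched linearly from sunset to the next sunrise. This
removes the seasonal shift in day length so activity densities from
different strata are comparable. Date-specific (not season-averaged)
anchoring is implemented; the two differ by at most a few minutes per
event here. One reference location (49.0° N, 13.4° E, the study-area
centroid, clock UTC+1) serves all cameras by default — the park spans
under half a degree, which moves sun times by under two minutes.

## Activity subsets and circular densities

Per species, events split into 24 subsets: effort (3) × placement (2) ×
recreation (2) × zone (2). The recreation split is a per-window median:
trail cameras at or above the median recreation RAI of that effort
window are "high", the rest "low" (ties to high — with 60 distinct
values this reproduces a 30/30 split), and each forest camera inherits
its paired trail camera's label. Subsets with fewer than 10 independent
events are dropped and reported.

Densities use a von Mises kernel,
`f(θ) = (1/n) Σ exp(κ cos(θ − tᵢ)) / (2π I₀(κ))`, on a 512-point
half-open grid. The concentration κ comes from a plug-in rule: the
kernel's circular SD is matched to `1.06 σ̂ n^(−1/5)` with
`σ̂ = sqrt(−2 log R̄)` the sample circular SD, inverting the Bessel-ratio
with Fisher's approximation. This is declared rather than inherited from
any package default so results are reproducible. Envelopes are pointwise
2.5/97.5 percentiles over resamples of the event times ("data"
bootstrap). The density is explicitly renormalized to integrate to one
(trapezoid over the periodic grid), and the estimator is equivariant
under circular shifts to grid precision.

## The beta-binomial nocturnality model

For camera *i* in stratum *s*, the night count among `n` events is
modelled as beta-binomial with mean `μ = logit⁻¹(xᵀβ)` and precision
`φ` (`α = μφ`, `β = (1−μ)φ`): binomial counts with a beta-distributed
success probability, absorbing the overdispersion that camera-level
clustering produces. The design uses treatment coding with reference
levels *high* effort and *trail* placement — coefficients read as
departures from the most-disturbed baseline — and the full three-way
expansion effort × placement × each continuous covariate (distance to
hunting zone, recreation RAI of the paired trail with the two high
windows pooled, and a visibility layer matched to species eye level:
140 cm for red deer, 70 cm for roe deer and wild boar, 50 cm for red
fox and lynx; the intermediate assignments are a package default).
Continuous covariates are z-scored after optional per-species
transforms (`log1p`, `sqrt`, quadratic), with scaling constants stored
for exact back-transformation. Species-specific transform lists are
configuration, not hard-coded, because residual-driven choices belong
to the analyst.

Estimation is maximum likelihood over `(β, log φ)` by BFGS, with
standard errors from the inverse observed information. This replaces
MCMC machinery deliberately: the scientific model is the likelihood and
covariate structure, and ML tests exactly that model; an optional
random-walk Metropolis sampler over the same posterior (weak `N(0,
2.5²)` priors on scaled coefficients) is provided for comparison. In
the orchestrated pipeline a weak Gaussian ridge (`penalty_sd = 2.5`)
stabilizes the heavily parameterized designs on sparse species;
unpenalized fits are the default elsewhere and are what the recovery
tests exercise. Correctness is checked three ways: special-case
reductions of the likelihood (Bernoulli, binomial limit, brute-force
pmf integration), agreement with an independent implementation
(glmmTMB's beta-binomial family) on simulated data, and a
parameter-recovery experiment (100 simulated datasets, 200 cameras,
~50 events each) requiring ≥95% of coefficients within 3 SEs of truth.

The predicted *nocturnality index* is `logit⁻¹(xᵀβ)` over a covariate
grid: 0.5 means equal day/night activity, and the index crosses 0.5
exactly where the linear predictor crosses zero.

## The synthetic-data generator

The generator's defaults are the study conditions: 61 paired locations,
a study window from 2020-11-15 to 2021-12-05, monthly hunting weights
(Feb–May 3, Jun–Sep 7, Oct–Jan 15 per month) that land the three strata
exactly in the <5% / 5–10% / >10% bands, 30% of locations in the
hunting zone with out-of-zone distances truncated-exponential (mean
1000 m, max 3933 m, matching the observed right-skewed range),
visibility covariates uniform within the observed ranges, daily outage
probability 0.02, and species base rates of a few events per 100
camera-days.

Event counts per camera-day are Poisson — the paper's index arithmetic
implies no particular generative model, and Poisson is the minimal
counting model under which the RAI estimates a rate unbiasedly. Event
*times* use a two-stage scheme: a Bernoulli night/day draw with
probability from the ground-truth nocturnality predictor for that
camera × stratum, then a clock time from the species' von Mises mixture
restricted to the night or day segment of that date. The two-stage
construction makes the beta-binomial model *correctly specified* under
the generator, which is what clean parameter recovery requires.
Recreation is trail-only, unimodal around 13:00 (SD 2.5 h), with a
configurable fraction of events emitted as multi-trigger bursts seconds
apart — so the 8 s rule is exercised deliberately.

What the generator does **not** emulate: animal movement and spatial
autocorrelation between cameras, detection-probability differences
between placements beyond the base-rate ratio, weather-driven outage
clustering, and seasonal changes in the circadian mixture itself.
Passing tests therefore demonstrate that the estimators recover the
truth under the stated model, not that the model captures every feature
of field data.

## Numerical choices and problem sizes

Bootstrap and envelope defaults are B = 1000 with fixed seeds; the test
suite uses smaller B (tens to hundreds) where only mechanics are under
test, and the heavier simulation checks use 200 datasets (coverage) and
100 fits (recovery) — sizes at which the Monte-Carlo error of the
checked proportions is well below the asserted margins. Degenerate
inputs are handled explicitly: zero trap days give missing RAIs with a
message, single-location bootstraps collapse to the point estimate,
all-zero hunting calendars and sub-10-event activity subsets are
refused, and undefined bootstrap replicates are dropped and counted.

## Known limitations

The trail index inherits the arbitrariness of the `+1` shift at very
low RAIs; the effort classifier assumes the calendar's total is the
right denominator (shares are computed over the study window); Wald
intervals on the nocturnality predictions understate uncertainty for
sparse species; and the solar ephemeris is not valid at polar latitudes
(it refuses rather than extrapolates). One published trail-index cell
(roe deer at low effort) is inconsistent with its own printed RAI
inputs at two decimals; the package reproduces the arithmetic, not the
misprint.
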