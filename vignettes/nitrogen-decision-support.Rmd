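---
title: "Methods: nitrogen decision strategies on a virtual putting green"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nitrogen decision strategies on a virtual putting green}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenkeeper)
```

## The problem and the simplification it rests on

Sand-based putting greens receive more nitrogen per unit area than any
other turf, with little objective guidance. On these root zones the N cycle
collapses to a short ledger: fertilizer (plus a small background
mineralization from soil organic matter) is the input, and clippings hauled
off the green at each mowing are the dominant output; leaching,
volatilization and denitrification are negligible under good practice. If
you can estimate how much the grass will grow, you can estimate how much N
it will remove, and replace exactly that. Everything in this package —
the four dosing strategies, the simulator, the budget arithmetic — is an
articulation of that ledger.

## The four strategies

**Growth potential (GP).** A Gaussian temperature index for cool-season
grass, `GP = exp(-0.5 ((T - 20)/5.5)^2)`, equal to 1 at the 20 °C optimum
and near 0 at 0 and 40 °C. The dose for an application event is the mean
GP over the lookback window times a calibrated maximum daily N use rate
times the interval length. The "maximum daily N use rate" is interpreted as
the nitrogen in the maximum daily growth (3.2 g m⁻² d⁻¹ × 3.9% tissue N =
0.1248 g N m⁻² d⁻¹): that is the only reading that reproduces the quoted
17.5 kg ha⁻¹ biweekly cap (0.1248 × 14 × 10 = 17.47). `calibrate_max_daily_n()`
re-derives the rate from any prior season's clipping record (default: its
maximum; the quantile is exposed because "maximum observed" is itself a
choice). Two open readings are settled as follows: the GP correction "of
the previous 14 days" is taken as the *arithmetic mean* of daily GP over
the window — the only reading under which the dose cannot exceed the cap —
and the first event of a season, with fewer than 14 days of history, uses
all available days, since fertilization begins at season start.

**Experience schedule.** 10 kg ha⁻¹ every second week, a fixed plan with no
feedback. It is both a strategy and the baseline all others are compared
against.

**NDRE threshold.** The normalized difference red edge index is calibrated
once against the *virtual reference*: turf held at minimally acceptable
visual quality 6 reads NDRE ≈ 0.28. If the mean NDRE of the preceding 14
days exceeds 0.28 the canopy is judged sufficient and N is withheld;
otherwise 10 kg ha⁻¹ is applied. Two conventions are fixed here: the window
is half-open, `(d − 14, d]`, *including* the decision morning's reading
(readings arrive ~3×/week, so excluding the decision day would sometimes
leave a 4-day-old window edge); and at a mean of exactly 0.28 the rule
fertilizes — withholding requires strictly greater, following the rule's
wording.

**Regression forest (ML-RF).** A random-forest regressor predicts clipping
mass per collection event from: mean soil moisture of the event and the
previous event, weekly traffic, NDRE, root-zone label, days between
mowings, the event day's weather (Tmax, Tmin, Tavg, precipitation, RHmax,
RHmin, RHavg, wind, reference ET) and the N applied in the trailing 14
days. Event predictions over the coming 14 days are summed and converted to
a dose by a three-branch replacement rule with target band
17.5–22.5 g m⁻²/2 wk (the clipping range observed at visual quality 6–7;
1.25 g m⁻² d⁻¹ × 14 = 17.5 exactly, while the upper bound is carried as the
stated 22.5 rather than 1.6 × 14 = 22.4):

* in band (inclusive at both ends): dose = predicted yield × 0.039 × 10;
* below band: dose from the band median, 20 × 0.039 × 10 = 7.8 kg ha⁻¹ —
  the source text prints "> 17.5" for this branch, but that contradicts
  branch 1 and its own account of season starts with predictions *below*
  the target range, so it is implemented as `y < 17.5`;
* above band (strictly): no N.

Because no forest implementation exists in the supported dependency set,
the package carries its own: CART regression trees on bootstrap resamples
with `mtry = p/3` feature subsampling, grown in C++ for speed, averaged at
prediction time. Defaults (500 trees, node size 5) follow regression-forest
convention; the fit is reproducible under a seed. Constant-target,
permutation-sanity, row-order-invariance and held-out-accuracy tests guard
the implementation.

The features used for a *future* interval are forecast-free persistence:
weather rows come from the supplied (realized) series, as a manager would
use station data; canopy and management readings persist from the latest
observation; the N-rate feature is the previous application. The
circularity risk of feeding the strategy's own doses back in is accepted
and confined to that one lagged feature.

## The virtual green

`run_season()` drives a daily state model:

* **Weather** — average temperature follows a half-sinusoid over the season
  (edges `mean_peak − amplitude`, mid-season peak `mean_peak`) plus AR(1)
  noise; defaults (peak 23 °C, amplitude 8, φ = 0.7, σ = 1.5 °C over 210
  days) give an upper-Midwest season with mean near 20 °C, deliberately
  sitting at the GP optimum where the contrast among strategies is
  sharpest. Humidity, precipitation (wet-day Bernoulli × exponential
  amounts), wind and a deterministic reference ET (increasing in
  temperature and dryness) complete the record.
* **Growth** — `Y = Gmax · GP(T) · f_N · f_water · f_traffic · ε`, with
  `Gmax = 3.2 g m⁻² d⁻¹` (the same maximum the GP dosing model is
  calibrated to), multiplicative lognormal noise ε (σ = 0.10, mean-one so
  totals are unbiased), a mild quadratic moisture penalty and a linear
  traffic penalty. The nitrogen factor is saturating,
  `f_N = f₀ + (1 − f₀)·P/(P + k_N)` in the soil pool `P`, with
  half-saturation `k_N = 0.5 g N m⁻²` and a small floor `f₀ = 0.05` of
  reserve-fuelled growth that does not draw on the pool. `k_N` was chosen
  once so that an unfertilized plot supplied only by mineralization
  produces roughly a quarter to a third of a well-fertilized plot's
  clippings; the floor makes a plot with a fully exhausted pool grow
  minimally instead of flatlining at zero.
* **Soil N pool** — `P ← P + fertilizer + mineralization − uptake`, uptake
  being the pool-drawing part of growth × 3.9%, capped by what the pool
  holds. The balance is exact by construction and asserted to 10⁻⁹ in the
  tests. The two default zones differ only in organic matter
  (mineralization 0.0102 vs 0.0144 g N m⁻² d⁻¹) and baseline moisture;
  that single contrast is what lets zone-specific recommendations emerge
  from the N-responsive strategies while the weather-only ones dose both
  zones identically.
* **NDRE** — a saturating function of N status,
  `ndre = 0.22 + 0.18·s/(s + k)`, with `k` solved at construction so that
  a canopy producing the quality-6 clipping rate at optimal temperature
  reads exactly 0.28; Gaussian sensor noise σ = 0.005. No functional form
  for NDRE vs N status is available from field data — only the
  0.28 ↔ quality-6 anchor and the observed 0.25–0.35 range — so this is a
  stand-in constrained by both, and conclusions that hinge on NDRE *shape*
  (rather than its ordering and anchor) should not be read off the
  simulator.
* **Quality** — piecewise linear in daily clipping through (1.25, 6) and
  (1.6, 7), descending below the lower anchor to the natural endpoint
  (0 clipping ↔ quality 1, completely dead turf), extending the anchor
  slope above, clipped to [1, 9]. The descent-to-zero choice replaces
  plain anchor-slope extrapolation downward because that slope never
  reaches quality 1 at zero growth (it stalls at 2.4), which contradicts
  both the scale's definition and the degenerate-input expectation.

Decisions fall on days 1, 15, 29, … so a 30-week season has 15 biweekly
events and the experience schedule totals exactly 150 kg ha⁻¹. On day 1 the
NDRE rule has no canopy history and fertilizes (sufficiency cannot be
established); the GP rule uses the single available day.

## The virtual trial and forest calibration

`run_trial()` mirrors the field design: when the forest strategy is
included, year 1 is a calibration year, and evaluation years follow with
every strategy on replicate plots (plus an always-included zero-N control
for NUE). The calibration year applies a fixed-dose N *gradient*
(0, 5, 10, 17.5 kg ha⁻¹ biweekly) on each zone rather than the experience
schedule alone. This matters: a forest only interpolates, and one trained
exclusively on well-fertilized turf has never seen a low-NDRE, low-yield
canopy — its predictions then stay in the training range and the
replacement rule locks into its zero-N branch while the plot starves. A
gradient is also what a real calibration data set spanning N rates looks
like. After each evaluation year, one replicate per zone and strategy
joins the training pool for the following year.

Seeds fan out from a single master seed through a counter-based integer
mix (`derive_seed()`), giving every plot, year and training run an
independent but fully reproducible stream; reports record all of them.

## Numerical and reporting conventions

Internal mass-per-area is g m⁻² throughout; kg ha⁻¹ appears only at
interfaces (× 10, exact). Doses are carried at full precision and rounded
only for display (0.1 kg ha⁻¹). Reported percentages round half away from
zero, matching hand-rounded tables. NUE is undefined (NA) for unfertilized
plots. Ratio summaries require strictly positive observed yields. The
forest breaks split ties toward the first best candidate and places
thresholds midway between distinct sorted values; categorical predictors
are integer-coded (exact for the binary zone label).

## What a green test does and does not establish

The simulator reproduces the *structure* of the system — an N-responsive,
temperature-driven crop with a closed clipping budget — and its headline
behaviors: the strategy ordering of cumulative N (GP ≥ experience ≥ ML-RF ≥
NDRE near the temperature optimum), zone specificity of the N-responsive
strategies only, GP's growth over-forecasting on a green that cannot
realize its temperature potential, and NDRE ≈ 0.28 at quality 6. It does
not emulate real-world N carryover in thatch and soil organic matter (all
unrecovered N stays in the pool, so simulated NUE runs high), spatial
variability within a green, measured tissue-N fluctuation (2.5–5% over a
season vs the fixed 3.9%), sensor drift, or weather forecast error. Passing
tests therefore certify the decision logic and the budget arithmetic, not
field performance.

## Known limitations

* The NDRE response shape is a calibrated stand-in (see above).
* Mineralization is constant within a season; real release tracks
  temperature and moisture.
* The forest's future-interval features persist the latest canopy reading
  over the whole interval; a fast-collapsing canopy is seen with up to two
  weeks' delay.
* Tree growth uses exhaustive splits on integer-coded categories, which is
  only exact for binary factors (the package's use); a many-level nominal
  factor would need proper subset splits.
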