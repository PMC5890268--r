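---
title: "Methods: drought-period flux analysis on a topographic catena"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought-period flux analysis on a topographic catena}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catenaflux)
```

`catenaflux` analyses soil CO2 and CH4 dynamics across ridge–slope–valley
catenas through drought events. This vignette describes the models each
stage implements, the assumptions behind them, the tunable parameters
and their defaults, the synthetic-data generator used to validate the
chain, and the design decisions taken where the methodology was
genuinely open.

## Chamber flux estimation

An automated chamber closure produces a concentration trace
$c(t)$ (CO2 in ppm, CH4 in ppb) over a nominal 10-minute deployment.
Two accumulation models are fitted to every closure:

* **linear**: $c(t) = a + bt$ by ordinary least squares; the flux rate
  is $b$;
* **exponential (saturating)**:
  $c(t) = c_\infty + (c_0 - c_\infty)e^{-kt}$, fitted by
  Levenberg–Marquardt nonlinear least squares. The reported rate is the
  fitted curve's tangent slope at $t = 0$, $k(c_\infty - c_0)$, because
  the headspace gradient feeds back on diffusion and suppresses the
  apparent rate as the chamber fills; the initial tangent is the
  pre-closure flux. Internally the curve is parameterized as
  $c(t) = c_0 + s_0(1 - e^{-kt})/k$ (with `expm1` for small $kt$), which
  makes $s_0$ — the quantity of interest — a direct parameter with a
  direct standard error, and degenerates smoothly to the straight line
  as $k \to 0$, so near-linear traces remain well conditioned. Fits are
  restarted over a small grid of initial $k$ values
  ($10^{-5}$–$10^{-2}$ s$^{-1}$) and the lowest-deviance convergent fit
  wins; total non-convergence is reported as a flagged estimate with
  infinite uncertainty, never an exception.

A concentration rate becomes a surface flux through the ideal-gas
bridge $F = (dc/dt) \cdot PV/(RTA)$ with chamber pressure $P$,
headspace volume $V$ (default 0.02951 m³), air temperature $T$, and
basal area $A$ (default 0.1824 m²). With ppm s⁻¹ in, the flux is
µmol m⁻² s⁻¹; with ppb s⁻¹, nmol m⁻² s⁻¹.

**Model selection** uses the uncertainty ratio se/|F|: the model with
the smaller ratio is kept, ties go to the simpler linear model, and if
both ratios exceed `max_uncertainty_ratio` (default 1.0) the closure is
dropped as `both_uncertain`.

**Quality control** (`qc_policy()`) drops closures that run under
9 min or over 11 min (540/660 s), whose initial concentration deviates
from ambient by more than `ambient_band` = 25% (a failed flush), or
whose covariates leave plausible bounds (T ∈ [10, 45] °C, RH ≤ 100%,
P ∈ [85, 110] kPa). The 25% band, the ratio threshold of 1.0 and the
covariate bounds are package choices — the underlying field protocol
says only "substantially" and "high values" — and are all exposed in
the policy object. The first 30 s of each closure (`deadband_s`) are
excluded from fits as a mixing artifact when running the batch
estimator; the low-level `fit_*` functions default to no deadband so
that textbook three-point examples behave literally.

## Drought-period segmentation

Drought periods are defined from the soil-moisture record itself, not
the rain gauge: the daily catena-mean volumetric moisture series
$y_1, \dots, y_n$ is partitioned into $m + 1$ segments, each fitted
with its own intercept and linear time trend. For fixed $m$ the
breakpoints minimize the total residual sum of squares, found exactly
by dynamic programming over a precomputed segment-RSS triangle (each
admissible segment's OLS RSS in closed form from cumulative sums).
Minimum segment length is $\lceil hn \rceil$ with $h = 0.15$.

The breakpoint count is selected by BIC,
$n\log(\mathrm{RSS}_m/n) + p_m \log n$ with
$p_m = 2(m+1) + m + 1$ (per-segment intercept and trend, $m$ break
positions, one error variance), over $m = 0, \dots,$ `max_breaks`
(default 4). A supF test — the maximum over admissible split points of
the F statistic comparing a single-break fit against the global fit —
provides the overall structural-change p-value; its null distribution
is obtained by simulating iid Gaussian series of the same length
(≥ 999 replicates; the statistic is location/scale invariant, so pure
noise suffices), with the add-one p-value correction. Simulation was
chosen over asymptotic response-surface approximations for exactness
at the series lengths involved and freedom from table lookups.

Aggregation and gaps: the series segmented is the daily mean over all
sensors (the per-position option remains available through
`select_n_breaks()` on any series); interior gaps up to 3 days are
linearly interpolated, longer gaps split the record and the longest
contiguous span is segmented, with a warning.

Two properties of this machinery are worth knowing. First, on iid
daily noise the BIC rule is sharply calibrated (essentially never
selecting spurious breaks at $n \approx 450$), but *autocorrelated*
daily noise degrades it quickly — low-frequency wander mimics regime
change, a generic weakness of information criteria under serial
correlation. Second, breakpoints marked by level steps are located to
within a few days, while breakpoints marked only by a slope change
(flat drought → rising recovery) are intrinsically softer, with date
errors occasionally reaching two to three weeks.

## Period × zone statistics

`summarize_period_zone()` reports n, mean, s.d., s.e.m. = s.d./√n and
the 90th percentile per drought-period × zone cell. Quantiles use the
type-7 (linear interpolation) convention throughout; this is stated
explicitly because hot-moment thresholds differ across conventions.

The flux ANOVA follows the field design: a two-way repeated-measures
ANOVA with drought period and topographic zone as predictors and the
chamber as subject, implemented as the univariate `aov` model
`y ~ period * zone + Error(chamber/period)` — zone (between-subject)
is tested in the chamber stratum, period and the interaction in the
chamber-by-period stratum. CO2 fluxes are log transformed (positive,
right-skewed); CH4 fluxes are sign-indefinite and are never
transformed. Tukey-adjusted pairwise contrasts come from `emmeans` on
the fitted strata (the model is fitted with sum-to-zero contrasts so
the marginal means are well defined). Chamber-day means are the
recommended observation unit to temper serial correlation between
consecutive closures; both observation-level and aggregated analyses
are possible since the function takes whatever table it is given.

Hot moments are observations above their period's 90th percentile;
at least 10 observations per period are required so the threshold is
interior to the data.

## Ecosystem upscaling

Cumulative CO2-equivalent emissions are simulated at a daily time step
over a 326-day study window starting 2015-02-10 (the start of chamber
sampling). Per simulation and day, each zone's flux is drawn
independently from Normal(mean, s.d.) of that day's period × zone
summary cell; zones are combined with catchment-area weights
(ridge 0.17, slope 0.65, valley 0.18); the weighted flux is converted
by $\mathrm{flux} \times 86400 \times 10^4 \times M \times
\mathrm{GWP} / 1000$ (kg CO2e ha⁻¹ day⁻¹; GWP = 34 for CH4, 1 for CO2;
$M$ the molar mass) and accumulated. The default 5000 simulations take
seconds. Negative CO2 draws are resampled (soil respiration is
non-negative); CH4 draws are untruncated because CH4 fluxes genuinely
change sign across the catena. Daily independence and normality are
the minimal reading of a "mean ± s.d." specification; no attempt is
made to model day-to-day flux autocorrelation, which would widen the
draw distribution of totals but not shift its mean.

The reported 95% interval is the Monte Carlo confidence interval of
the *mean* total, mean ± 1.96·sd/√n_sims. This convention is the one
consistent with published cumulative-emission intervals (which are far
too narrow to be draw percentiles) and has the expected behaviour that
quadrupling the simulation count halves the width; the raw simulated
totals are returned for anyone who prefers draw quantiles.

The **offset statistic** compares the post-drought CH4 rebound against
the drought + recovery CH4 sink: cumulative CH4 CO2e is simulated over
the sink window (first to third breakpoint) and over the first 50 days
after the third breakpoint, the ratio rebound/|sink| is formed per
paired draw, and draws without a net sink are excluded and counted.
The ratio's CI may exceed 100%. The 50-day rebound window is allowed
to extend past the 326-day study window, since the window end is not
tied to the sampling calendar.

Scope note: reproducing specific published ecosystem totals requires
the full deposited flux dataset (recovery-period zone means were never
printed); the package reproduces the *procedure* and validates it
against closed-form expectations and scaling laws instead.

## The synthetic catena generator

The generator emulates the study conditions so that every downstream
stage can be tested against ground truth. Its defaults *are* those
conditions: five transects of seven positions, hourly records from
2014-11-01 to 2016-02-01, moisture-regime breakpoints at 2015-04-25,
2015-08-24 and 2015-11-24, ridge moisture falling 0.36 → 0.13 v/v and
valley 0.51 → 0.37, valley O2 rising 5.6 → 11.2%, the published
period × zone flux means and s.d.s (slope CO2 3.79 ± 2.92 →
6.06 ± 4.26 µmol m⁻² s⁻¹; valley CH4 17.43 ± 29.60 →
1.67 ± 4.09 nmol m⁻² s⁻¹; post-drought rebounds 10.12/15.16), a
2035 mm drought year against a 4219 mm ten-year baseline, and
soil-chemistry effect sizes (valley organic P × 4.01, inorganic
P − 60%).

Structure of the sensor model, per position:

* a regime mean path: flat at the period mean within each period, with
  level discontinuities smoothed linearly over a 14-day window
  *centred* on the breakpoint (centring keeps within-period sample
  means within ~0.003 v/v of the configured means, inside 2 s.e. under
  default noise). The recovery period is declared a *trending* regime
  (`ramp = "from_previous"` in the regime table): its path runs
  linearly from the drought level to the reflection
  $2\mu_{rec} - \mu_{dr}$, so the period averages to its configured
  mean while representing the gradual 12-week rewetting that makes
  recovery a distinct regime in the first place;
* per-sensor hourly AR(1) noise with coefficient 0.9 (hourly field
  data are strongly autocorrelated) at the per-period marginal s.d.;
* a catena-shared daily component (s.d. 0.03 v/v) representing
  rain-event forcing common to all sensors. Without it, averaging 35
  independent sensors would shrink catena-mean noise to ~0.001 v/v and
  make the daily series unrealistically smooth. The shared component
  is white from day to day: daily rainfall totals carry little
  day-scale memory, sub-daily persistence already lives in the hourly
  AR(1), and — as noted above — persistent shared wander would be
  indistinguishable from regime structure for *any* information
  criterion, ours included.

Chamber traces are generated by inverting the estimator's own forward
model: a true flux drawn from the period × zone mixture (Gaussian bulk
plus, for CH4, a lognormal hot-moment component
$\mu + \sigma \cdot 4 \cdot \mathrm{LogN}(0, 0.75)$ at weights
0.02–0.05 — the printed valley CH4 s.d. far exceeding its mean implies
strong right skew, and hot moments must live in the far tail to raise
the 90th percentile without dragging the median), converted to a
concentration slope, run through the linear or saturating path, plus
iid analyzer noise (0.5 ppm CO2, 2 ppb CH4). True CO2 fluxes are
resampled to be positive. Malfunctions — short/long closures, failed
flushes (30–60% ambient offset), covariate spikes, outage days — are
injected with configurable probabilities and recorded in the truth
table, so QC tests can demand *exact* identification when the policy
thresholds bracket the injected faults.

Unpublished cells are handled openly: all recovery-period flux and
moisture means are interpolations between drought and post-drought
values, the ridge drought CH4 mean is reconstructed as 1.76 × the
pre-drought sink (a "76% sink increase"), and the valley pre-drought
CO2 mean is set so the drought value realizes the published 163%
increase. Each such cell is flagged (`basis` column /
`interpolated_periods` truth field).

What passing tests on this generator do **not** show about real data:
real moisture carries persistent shared wander that, as discussed,
will push BIC toward extra breakpoints (segmenting real records may
warrant a stricter criterion or pre-whitening); real flux
distributions are skewed in the bulk, not just the tail, so Gaussian
cell summaries understate quantile spreads; and real chamber
malfunctions are not cleanly separable classes.

## Numerical and testing choices

Degenerate inputs: constant traces yield zero slope with zero se under
both models; zero-residual fits report se = 0 when the covariance
degenerates; flat series give supF = 0 with p = 1; a series too short
for its breakpoint count, a missing regime/summary cell, an empty
ANOVA design cell, or unordered sample times are immediate errors
naming the offender, never silent repairs. All randomness flows from
explicit integer seeds; repeated runs are byte-identical, distinct
seeds give distinct outputs.

Problem sizes in the test-suite experiments were chosen to keep each
statistical check's own Monte Carlo error well below what it asserts:
50 replicate drought years for breakpoint recovery, 500 replicates for
ANOVA type-I calibration (binomial s.e. ≈ 1% at the 5% level), 60 for
power, 200 random cases for the DP-versus-exhaustive-search
equivalence (n ≤ 60, up to 3 breaks), and 5000 Monte Carlo simulations
(the published convention) for upscaling checks.

## Known limitations

* Periods are defined on moisture alone (no multivariate or O2-based
  segmentation), matching the source design.
* The repeated-measures ANOVA is the classical univariate `aov`
  construction; no sphericity correction, random slopes or GLS with AR
  errors are offered — the design is reproduced, not improved.
* No water-vapour dilution correction in the flux bridge.
* Positions are statistically, not physically, coupled; there is no
  hydrological routing along the catena.
* The Monte Carlo draws one flux per day per zone (not per chamber);
  with the published zone-level s.d.s this is the faithful reading,
  but it folds chamber-to-chamber spread into day-to-day spread.
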