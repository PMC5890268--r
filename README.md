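# catenaflux

Drought-period soil greenhouse-gas analysis for topographic catenas.

Humid tropical forest soils cycle carbon fast and under fluctuating
redox: ridges are dry and oxic, valley bottoms wet and hypoxic, and a
severe drought reorganizes the whole gradient within weeks — CO2
emissions rise, the soil CH4 sink deepens, and a post-drought CH4
rebound can undo the drought-period sink in a matter of weeks. Testing
such claims requires a chain of analyses that each carry their own
subtleties: turning automated chamber concentration traces into
quality-controlled surface fluxes, deciding objectively *when* the
drought started and ended from the soil-moisture record rather than the
rain gauge, comparing fluxes across drought periods and topographic
zones, and upscaling chamber-point measurements to ecosystem
CO2-equivalent budgets with honest uncertainty.

`catenaflux` implements that chain for ridge–slope–valley sensor/chamber
networks, together with a synthetic catena generator so every stage is
testable against known ground truth:

* **Chamber flux estimation** — for each closure both a linear model and
  a saturating exponential model `c(t) = c_inf + (c0 − c_inf)e^{−kt}`
  are fitted; the reported rate is the t = 0 tangent slope, converted to
  a surface flux via the ideal-gas bridge `F = (dc/dt)·PV/(RTA)`. The
  model with the smaller uncertainty ratio se/|F| wins; closures outside
  9–11 min, failed flushes (initial concentration off ambient by more
  than 25%), anomalous covariates, or fluxes where both models are
  uncertain are flagged and dropped.
* **Drought-period segmentation** — the daily catena-mean moisture
  series is split by globally optimal piecewise-linear regression
  (dynamic programming over a segment-RSS triangle, minimum segment
  fraction h = 0.15); the breakpoint count is chosen by BIC with
  parameter count `(m+1)k + m + 1`, and a supF structural-change test
  with a simulated null gives the overall p-value.
* **Period × zone statistics** — cell summaries (mean, s.d., s.e.m.,
  type-7 90th percentile), two-way repeated-measures ANOVA with the
  chamber as subject (`aov` error strata) and Tukey HSD contrasts, and
  hot-moment detection as observations above the per-period 90th
  percentile.
* **Ecosystem upscaling** — daily-time-step Monte Carlo: each simulated
  day draws a zone flux from Normal(mean, s.d.) of its drought-period ×
  zone cell, weights zones by catchment area (ridge 17%, slope 65%,
  valley 18%), converts to kg CO2e ha⁻¹ day⁻¹ with 100-year GWPs
  (CH4 = 34), and accumulates over the study window; a baseline scenario
  holds pre-drought conditions fixed, and the sink/rebound offset
  statistic compares the post-drought CH4 rebound against the
  drought-period sink.

## Worked example

Simulate a drought year on the default five-transect, seven-position
catena, recover the drought periods from the moisture record, and put a
Monte Carlo budget on the drought-period CH4 sink:

```r
library(catenaflux)

cfg <- catena_config(seed = 1)          # breakpoints 2015-04-25 / 08-24 / 11-24
sim <- generate_sensor_series(cfg)      # 383,915 hourly sensor rows
seg <- segment_moisture(sim$sensors)
seg
#> Piecewise-linear segmentation (n = 458 )
#>   chosen breakpoints: 3
#>   at index: 178, 276, 389 (2015-04-27, 2015-08-03, 2015-11-24)
#>   supF = 859.8 , p = 0.001
```

BIC picks three breakpoints (the generator's truth), two of the three
recovered dates land within days of the true regime shifts, and the
supF test rejects "no structural change" at the resolution of its 999
simulated null replicates. The BIC table is in `seg$bic_table`.

```r
summ <- default_flux_regimes()[, c("period", "zone", "gas", "mean", "sd")]
mc <- run_monte_carlo(summ, upscaling_config(seed = 1), gas = "CH4",
                      window = as.Date(c("2015-04-25", "2015-11-23")))
mc
#> Cumulative CH4 emissions, observed scenario: -91.64 kg CO2e ha-1
#>   (95% CI -91.88--91.40) over 213 days
```

Under the published zone means the drought + recovery window is a net
ecosystem CH4 *sink* of ~92 kg CO2e ha⁻¹ (negative = uptake): drought
aeration deepens ridge and slope CH4 consumption faster than it
suppresses valley emission. The unit bridge is available directly:
`flux_to_daily_co2e(1, "CH4")` returns 0.4712 kg CO2e ha⁻¹ day⁻¹ for a
sustained 1 nmol CH4 m⁻² s⁻¹.

The full pipeline (simulate → fluxes → segment → summarize → upscale)
runs from one configuration object:

```r
run_pipeline(pipeline_config(seed = 1), "out/")
```

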