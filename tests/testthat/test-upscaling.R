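# Zone weighting, CO2e conversion, Monte Carlo accumulation, and the
# sink/rebound offset statistic.

test_that("zone-weighted mean matches hand arithmetic and validates weights", {
  w <- c(ridge = 0.17, slope = 0.65, valley = 0.18)
  expect_equal(zone_weighted_mean(c(ridge = 2, slope = 2, valley = 2), w), 2)
  # 0.17*(-1.13) + 0.65*(-1.93) + 0.18*1.67, by hand
  expect_equal(zone_weighted_mean(
    c(ridge = -1.13, slope = -1.93, valley = 1.67), w), -1.146,
    tolerance = 1e-10)
  expect_error(zone_weighted_mean(c(ridge = 1, slope = 1, valley = 1),
                                  c(ridge = 0.5, slope = 0.6,
                                    valley = 0.18)), "sum to 1")
  expect_error(zone_weighted_mean(c(ridge = 1, slope = 1), w), "exactly")
})

test_that("the weighted drought CH4 flux from published zone means is a net sink", {
  fr <- default_flux_regimes()
  ch4 <- fr[fr$gas == "CH4" & fr$period == "drought", ]
  v <- stats::setNames(ch4$mean, ch4$zone)
  expect_lt(zone_weighted_mean(v[c("ridge", "slope", "valley")],
                               c(ridge = 0.17, slope = 0.65,
                                 valley = 0.18)), 0)
})

test_that("flux-to-CO2e conversion matches the dimensional-analysis oracle", {
  cfg <- upscaling_config()
  expect_equal(flux_to_daily_co2e(0, "CH4", cfg), 0)
  oracle <- 1e-9 * 86400 * 1e4 * 16.04 * 34 / 1000
  expect_equal(flux_to_daily_co2e(1, "CH4", cfg), oracle,
               tolerance = 1e-12)
  # sign preserved; CO2 path uses GWP 1
  expect_lt(flux_to_daily_co2e(-1, "CH4", cfg), 0)
  expect_equal(flux_to_daily_co2e(1, "CO2", cfg),
               1e-6 * 86400 * 1e4 * 44.01 / 1000, tolerance = 1e-12)
  expect_error(flux_to_daily_co2e(1, "N2O", cfg), "N2O")
})

test_that("zero-variance inputs give a zero-width CI equal to the closed form", {
  s <- toy_summaries(means = c(2, 3, 1.5, 4), sds = 0)
  cfg <- upscaling_config(n_sims = 200, seed = 42)
  mc <- run_monte_carlo(s, cfg, gas = "CO2")
  expect_equal(mc$ci_low, mc$ci_high)
  expect_equal(mc$total, expected_cumulative_emissions(s, cfg, "CO2"),
               tolerance = 1e-9)
  # linearity: scaling all means scales the total
  s2 <- s; s2$mean <- 2 * s2$mean
  mc2 <- run_monte_carlo(s2, cfg, gas = "CO2")
  expect_equal(mc2$total, 2 * mc$total, tolerance = 1e-9)
})

test_that("Monte Carlo mean matches the closed-form expectation within 3 MC se", {
  s <- toy_summaries(means = c(5, 8, 3, 6), sds = c(2, 3, 1, 2))
  cfg <- upscaling_config(n_sims = 5000, seed = 7)
  mc <- run_monte_carlo(s, cfg, gas = "CH4")
  mc_se <- sd(mc$draws) / sqrt(cfg$n_sims)
  expect_lt(abs(mc$total - expected_cumulative_emissions(s, cfg, "CH4")),
            3 * mc_se)
})

test_that("CI width halves when the simulation count quadruples", {
  s <- toy_summaries(means = c(5, 8, 3, 6), sds = c(2, 3, 1, 2))
  w <- vapply(c(2000L, 8000L), function(ns) {
    mc <- run_monte_carlo(s, upscaling_config(n_sims = ns, seed = 11),
                          gas = "CH4")
    mc$ci_high - mc$ci_low
  }, numeric(1))
  expect_equal(w[2] / w[1], 0.5, tolerance = 0.2)
})

test_that("totals decompose additively over periods and runs are seed-deterministic", {
  s <- toy_summaries(means = c(1, -2, 3, 0.5), sds = c(1, 2, 0.5, 1))
  cfg <- upscaling_config(n_sims = 500, seed = 19)
  mc <- run_monte_carlo(s, cfg, gas = "CH4")
  expect_equal(rowSums(mc$draws_by_period), mc$draws, tolerance = 1e-9)
  expect_equal(mc$total, sum(mc$per_period), tolerance = 1e-9)
  mc2 <- run_monte_carlo(s, cfg, gas = "CH4")
  expect_identical(mc$draws, mc2$draws)
})

test_that("a missing summary cell is an error naming the cell", {
  s <- toy_summaries(means = c(2, 3, 1.5, 4), sds = 1)
  s <- s[!(s$period == "recovery" & s$zone == "slope" & s$gas == "CO2"), ]
  expect_error(run_monte_carlo(s, upscaling_config(n_sims = 50), "CO2"),
               "recovery, slope, CO2")
})

test_that("baseline scenario holds the pre-drought cell over the whole window", {
  s <- toy_summaries(means = 1, sds = 0)
  s$mean[s$period == "pre_drought" & s$gas == "CO2"] <- 2
  cfg <- upscaling_config(n_sims = 100, seed = 3)
  base <- run_monte_carlo(s, cfg, "CO2", scenario = "baseline")
  days <- cfg$study_days
  expect_equal(base$total,
               days * flux_to_daily_co2e(2, "CO2", cfg), tolerance = 1e-9)
})

test_that("offset statistic is exact for equal sink and rebound, and flags non-sinks", {
  sink <- rep(-10, 100)
  off <- offset_fraction(sink, rebound_draws = rep(10, 100))
  expect_equal(off$offset_pct, 100)
  expect_equal(off$ci_low_pct, off$ci_high_pct)
  mixed <- c(rep(-10, 98), 0, 5)
  off2 <- offset_fraction(mixed, rebound_draws = rep(10, 100))
  expect_equal(off2$n_excluded, 2L)
  expect_error(offset_fraction(rep(1, 10), rep(1, 10)), "no draw")
})

test_that("offset CI straddles 100% when the rebound distribution is wide", {
  s <- toy_summaries(means = 0, sds = 1)
  s$mean[s$gas == "CH4" & s$period %in% c("drought", "recovery")] <- -1.15
  s$mean[s$gas == "CH4" & s$period == "post_drought"] <- 4.9
  s$sd[s$gas == "CH4" & s$period == "post_drought"] <- 12
  cfg <- upscaling_config(n_sims = 3000, seed = 29)
  sink <- run_monte_carlo(s, cfg, "CH4",
                          window = c(cfg$breakpoint_dates[1],
                                     cfg$breakpoint_dates[3] - 1))
  reb <- run_monte_carlo(s, cfg, "CH4",
                         window = c(cfg$breakpoint_dates[3],
                                    cfg$breakpoint_dates[3] + 49))
  off <- offset_fraction(sink$draws, reb$draws)
  expect_lt(off$ci_low_pct, 100)
  expect_gt(off$ci_high_pct, 100)
})
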