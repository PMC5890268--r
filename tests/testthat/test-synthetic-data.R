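# Synthetic catena data generators: ground-truth structure, published
# anchor values, determinism under seeds.

short_cfg <- function(seed = 1) {
  catena_config(start_date = as.Date("2014-12-01"),
                end_date = as.Date("2015-06-01"),
                breakpoint_dates = as.Date(c("2015-01-15", "2015-03-01",
                                             "2015-04-15")),
                seed = seed)
}

test_that("noise-free flat-regime series sits piecewise-exactly at the period means", {
  cfg <- short_cfg()
  cfg$transition_days <- 0
  reg <- default_sensor_regimes(cfg)
  reg$moisture_sd <- 0; reg$o2_sd <- 0; reg$temp_sd <- 0
  reg$ramp <- "none"
  ridge_means <- c(pre_drought = 0.36, drought = 0.13,
                   recovery = 0.25, post_drought = 0.36)
  reg$moisture_mean <- unname(ridge_means[reg$period])
  sim <- generate_sensor_series(cfg, reg, shared_sd = 0)
  one <- sim$sensors[sim$sensors$transect == 1 & sim$sensors$position == 1, ]
  one$period <- assign_period(one$date, cfg$breakpoint_dates)
  for (p in drought_periods()) {
    vals <- one$moisture[one$period == p]
    expect_equal(vals, rep(unname(ridge_means[p]), length(vals)),
                 tolerance = 1e-12)
  }
})

test_that("a missing regime cell raises an error naming the cell", {
  cfg <- short_cfg()
  reg <- default_sensor_regimes(cfg)
  reg <- reg[!(reg$period == "drought" & reg$position == 3), ]
  expect_error(generate_sensor_series(cfg, reg),
               "period=drought, position=3")
})

test_that("default ridge moisture reproduces the published pre-drought and drought means", {
  cfg <- catena_config(seed = 1)
  sim <- generate_sensor_series(cfg)
  ridge <- sim$sensors[sim$sensors$position == 1, ]
  ridge$period <- assign_period(ridge$date, cfg$breakpoint_dates)
  m <- tapply(ridge$moisture, ridge$period, mean)
  # 0.02 is ~2 s.e. of a period mean under the default noise model
  # (shared daily component dominates the catena-scale uncertainty)
  expect_lt(abs(m[["pre_drought"]] - 0.36), 0.02)
  expect_lt(abs(m[["drought"]] - 0.13), 0.02)
})

test_that("sensor generator is deterministic under seed and distinct across seeds", {
  cfg <- short_cfg(seed = 9)
  a <- generate_sensor_series(cfg)
  b <- generate_sensor_series(cfg)
  expect_identical(a$sensors, b$sensors)
  c3 <- generate_sensor_series(short_cfg(seed = 10))
  expect_false(identical(a$sensors$moisture, c3$sensors$moisture))
})

test_that("O2 decreases and moisture increases from ridge to valley within each period", {
  reg <- default_sensor_regimes(catena_config())
  for (p in drought_periods()) {
    sub <- reg[reg$period == p, ]
    sub <- sub[order(sub$position), ]
    expect_true(all(diff(sub$o2_mean) <= 0))
    expect_true(all(diff(sub$moisture_mean) >= 0))
  }
})

test_that("rainfall hits the drought-year and baseline annual totals", {
  cfg <- catena_config(seed = 3)
  rf <- generate_rainfall(cfg, baseline_annual_mm = 4219,
                          drought_annual_mm = 2035)
  yr <- format(rf$rainfall$date, "%Y")
  sums <- tapply(rf$rainfall$rain_mm, yr, sum)
  expect_gte(sums[["2015"]], 2034)
  expect_lte(sums[["2015"]], 2036)
  base <- sums[names(sums) != "2015"]
  expect_length(base, 10)
  expect_true(all(abs(base - 4219) < 1))
  expect_true(all(rf$rainfall$rain_mm >= 0))
})

test_that("rainfall anomaly is centred near zero when baseline equals the drought total", {
  cfg <- catena_config(seed = 5)
  rf <- generate_rainfall(cfg, baseline_annual_mm = 2035,
                          drought_annual_mm = 2035)
  an <- rainfall_anomaly(rf$rainfall, rf$climatology)
  expect_lt(abs(mean(an$anomaly_mm)), 0.5)
  expect_identical(rf$rainfall,
                   generate_rainfall(cfg, 2035, 2035)$rainfall)
  expect_error(generate_rainfall(cfg, -1, 2035), "positive")
})

test_that("zero CH4 flux with no noise yields a flat trace at ambient", {
  cfg <- short_cfg()
  fr <- default_flux_regimes()
  fr$sd <- 0; fr$hot_weight <- 0
  fr$mean[fr$gas == "CH4"] <- 0
  tr <- generate_chamber_traces(cfg, fr, dates = cfg$start_date,
                                closures_per_day = 1,
                                noise_sd = c(CO2 = 0, CH4 = 0))
  for (trace in tr$traces)
    expect_equal(trace$samples$ch4_ppb,
                 rep(1900, nrow(trace$samples)), tolerance = 1e-12)
})

test_that("with malfunction probabilities zero all closures run 10 min and pass QC", {
  cfg <- short_cfg()
  tr <- generate_chamber_traces(cfg, dates = cfg$start_date,
                                closures_per_day = 2)
  expect_true(all(vapply(tr$traces, `[[`, numeric(1), "duration_s") == 600))
  fx <- estimate_fluxes(tr$traces)
  co2 <- fx[fx$gas == "CO2", ]
  expect_true(all(co2$retained))
  expect_true(all(tr$truth$malfunction == ""))
})

test_that("a zone without a flux regime raises an error", {
  cfg <- short_cfg()
  fr <- default_flux_regimes()
  fr <- fr[!(fr$zone == "valley" & fr$gas == "CH4" &
               fr$period == "pre_drought"), ]
  expect_error(generate_chamber_traces(cfg, fr, dates = cfg$start_date,
                                       closures_per_day = 1),
               "pre_drought, valley, CH4")
})

test_that("soil chemistry encodes the published valley organic P drought response", {
  cm <- default_soil_chem_means()
  pre <- cm$mean[cm$period == "pre_drought" & cm$zone == "valley" &
                   cm$analyte == "organic_p"]
  dr <- cm$mean[cm$period == "drought" & cm$zone == "valley" &
                  cm$analyte == "organic_p"]
  expect_equal(dr / pre, 4.01, tolerance = 1e-3)  # a +301% increase
  # zero noise reproduces cell means exactly
  cfg <- short_cfg()
  cm0 <- cm; cm0$sd <- 0
  sc <- generate_soil_chem(cfg, cm0)
  merged <- merge(sc$soil_chem, cm0,
                  by = c("period", "zone", "analyte"))
  expect_equal(merged$value, merged$mean, tolerance = 1e-12)
  expect_identical(generate_soil_chem(cfg)$soil_chem,
                   generate_soil_chem(cfg)$soil_chem)
  bad <- cm; bad$mean[1] <- NaN
  expect_error(generate_soil_chem(cfg, bad), "finite")
})

test_that("flux mixture sample moments converge to configured moments at n = 1e4", {
  cell <- data.frame(mean = 3.79, sd = 2.92, hot_weight = 0, hot_mult = 0)
  set.seed(404)
  x <- catenaflux:::draw_flux(1e4, cell)
  expect_lt(abs(mean(x) - 3.79), 3 * 2.92 / sqrt(1e4))
  expect_lt(abs(sd(x) - 2.92), 3 * 2.92 / sqrt(2 * 1e4))
})

test_that("hot-moment mixture weight >= 0.5 is rejected", {
  cell <- data.frame(mean = 1, sd = 1, hot_weight = 0.6, hot_mult = 2)
  expect_error(catenaflux:::draw_flux(5, cell), "weight")
})
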