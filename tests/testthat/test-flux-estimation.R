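# Chamber flux estimation: model fits against analytic oracles, the unit
# bridge, uncertainty-ratio model selection and QC behaviour.

test_that("linear fit recovers flat and exact-line traces with zero se", {
  flat <- make_trace(co2_fun = function(t) rep(400, length(t)))
  f <- fit_linear(flat, "CO2")
  expect_equal(f$slope, 0)
  expect_equal(f$slope_se, 0)
  line <- make_trace(co2_fun = function(t) 400 + 0.02 * t)
  f2 <- fit_linear(line, "CO2")
  expect_equal(f2$slope, 0.02, tolerance = 1e-12)
  expect_lt(f2$slope_se, 1e-12)
})

test_that("linear fit matches the closed-form normal-equations oracle on noisy data", {
  set.seed(21)
  t <- seq(0, 600, by = 15)
  c_ppm <- 400 + 0.015 * t + rnorm(length(t), 0, 0.8)
  tr <- make_trace(co2_fun = function(x) c_ppm)
  f <- fit_linear(tr, "CO2")
  # independent oracle: explicit normal equations
  n <- length(t)
  b <- (n * sum(t * c_ppm) - sum(t) * sum(c_ppm)) /
    (n * sum(t^2) - sum(t)^2)
  a <- mean(c_ppm) - b * mean(t)
  se <- sqrt(sum((c_ppm - a - b * t)^2) / (n - 2) / sum((t - mean(t))^2))
  expect_equal(f$slope, b, tolerance = 1e-12)
  expect_equal(f$slope_se, se, tolerance = 1e-12)
})

test_that("exponential fit recovers a forward-simulated saturating trace", {
  k <- 0.005; c0 <- 400; cinf <- 500
  tr <- make_trace(co2_fun = function(t) cinf + (c0 - cinf) * exp(-k * t))
  f <- fit_exponential(tr, "CO2")
  expect_true(f$converged)
  expect_equal(f$slope, k * (cinf - c0), tolerance = 1e-6)
  expect_equal(f$k, k, tolerance = 1e-4)
})

test_that("exponential fit degenerates to the linear fit for near-linear data", {
  # curvature k * t_max = 0.006 << 1
  k <- 1e-5; slope0 <- 0.02; cinf <- 400 + slope0 / k
  tr <- make_trace(co2_fun = function(t) cinf - (slope0 / k) * exp(-k * t))
  fe <- fit_exponential(tr, "CO2")
  fl <- fit_linear(tr, "CO2")
  expect_true(fe$converged)
  expect_lt(abs(fe$slope - fl$slope) / abs(fl$slope), 0.01)
})

test_that("constant trace gives a zero initial slope under the exponential model", {
  tr <- make_trace(co2_fun = function(t) rep(415, length(t)))
  f <- fit_exponential(tr, "CO2")
  expect_equal(f$slope, 0)
  expect_equal(f$slope_se, 0)
})

test_that("concentration-to-flux bridge matches the dimensional-analysis oracle", {
  tr <- make_trace(temp_c = 25, press_kpa = 101.325)
  expect_equal(concentration_rate_to_flux(0, tr), 0)
  oracle <- 0.01 * 101325 * 0.02951 / (8.314462618 * 298.15 * 0.1824)
  expect_equal(concentration_rate_to_flux(0.01, tr), oracle,
               tolerance = 1e-12)
  tr2 <- make_trace(volume_m3 = 2 * 0.02951)
  expect_equal(concentration_rate_to_flux(0.01, tr2),
               2 * concentration_rate_to_flux(0.01, tr), tolerance = 1e-12)
  tr_bad <- make_trace(temp_c = -300)
  expect_error(concentration_rate_to_flux(0.01, tr_bad), "temperature")
})

test_that("model selection minimizes the uncertainty ratio with a linear tie-break", {
  pol <- qc_policy()
  s <- select_model(list(flux = 1, se = 0.1), list(flux = 1, se = 0.4), pol)
  expect_equal(s$model, "linear")
  expect_true(s$retained)
  s2 <- select_model(list(flux = 1, se = 1.5), list(flux = 1, se = 2), pol)
  expect_false(s2$retained)
  expect_equal(s2$qc_flags, "both_uncertain")
  s3 <- select_model(list(flux = 2, se = 0.5), list(flux = 2, se = 0.5), pol)
  expect_equal(s3$model, "linear")
})

test_that("QC flags short deployments, flush failures and bad covariates", {
  pol <- qc_policy()
  est <- list(flux = 1, se = 0.1, model = "linear",
              uncertainty_ratio = 0.1, qc_flags = character(0),
              retained = TRUE)
  short <- make_trace(duration_s = 480)
  q <- qc_filter(short, est, pol, "CO2")
  expect_true("short_deployment" %in% q$qc_flags)
  expect_false(q$retained)
  clean <- make_trace(duration_s = 600)
  expect_true(qc_filter(clean, est, pol, "CO2")$retained)
  flush <- make_trace(co2_fun = function(t) 800 + 0 * t)
  expect_true("flush_failure" %in%
                qc_filter(flush, est, pol, "CO2")$qc_flags)
  hot <- make_trace(temp_c = 60)
  expect_true("covariate_out_of_bounds" %in%
                qc_filter(hot, est, pol, "CO2")$qc_flags)
})

test_that("noise-free forward-simulated traces are recovered below 1e-6 relative error", {
  cfg <- catena_config(seed = 2)
  for (mode in c("linear", "exponential")) {
    tr <- generate_chamber_traces(cfg, dates = as.Date("2015-03-05"),
                                  closures_per_day = 1,
                                  trace_model = mode,
                                  noise_sd = c(CO2 = 0, CH4 = 0))
    fx <- estimate_fluxes(tr$traces)
    m <- merge(fx, tr$truth, by.x = "trace_idx", by.y = "closure_id")
    m$true <- ifelse(m$gas == "CO2", m$true_co2, m$true_ch4)
    expect_lt(max(abs(m$flux - m$true) / pmax(abs(m$true), 1e-9)), 1e-6)
  }
})

test_that("estimates are unbiased and RMSE shrinks with analyzer noise", {
  cfg <- catena_config(seed = 6)
  rmse <- vapply(c(2, 0.5), function(noise) {
    tr <- generate_chamber_traces(cfg, dates = as.Date("2015-03-05"),
                                  closures_per_day = 4,
                                  noise_sd = c(CO2 = noise, CH4 = 4 * noise))
    fx <- estimate_fluxes(tr$traces)
    m <- merge(fx[fx$gas == "CO2", ], tr$truth,
               by.x = "trace_idx", by.y = "closure_id")
    err <- m$flux - m$true_co2
    expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)) + 1e-4)
    sqrt(mean(err^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("uptake traces yield negative fluxes under both models", {
  sl <- slope_for_flux(-2)  # CO2 uptake, µmol m-2 s-1
  lin <- make_trace(co2_fun = function(t) 400 + sl * t)
  expect_lt(concentration_rate_to_flux(fit_linear(lin, "CO2")$slope, lin), 0)
  k <- 0.002
  ex <- make_trace(co2_fun = function(t)
    (400 + sl / k) - (sl / k) * exp(-k * t))
  fe <- fit_exponential(ex, "CO2")
  expect_true(fe$converged)
  expect_lt(concentration_rate_to_flux(fe$slope, ex), 0)
})

test_that("loosening every QC threshold never reduces the retained count", {
  cfg <- catena_config(seed = 13)
  tr <- generate_chamber_traces(
    cfg, dates = as.Date("2015-03-05"), closures_per_day = 4,
    malfunctions = malfunction_spec(p_short = 0.2, p_long = 0.2,
                                    p_failed_flush = 0.2,
                                    p_bad_covariate = 0.1))
  tight <- qc_policy()
  loose <- qc_policy(min_duration_s = 300, max_duration_s = 1000,
                     ambient_band = 0.8, temp_bounds_c = c(0, 70),
                     press_bounds_kpa = c(50, 150),
                     max_uncertainty_ratio = 10)
  n_tight <- sum(estimate_fluxes(tr$traces, tight)$retained)
  n_loose <- sum(estimate_fluxes(tr$traces, loose)$retained)
  expect_gte(n_loose, n_tight)
})
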