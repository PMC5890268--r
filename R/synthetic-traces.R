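# Synthetic chamber closures: true fluxes drawn from period x zone
# mixtures, inverted through the chamber concentration model of the flux
# estimator, with optional injected malfunctions.

#' Default period x zone flux regime table
#'
#' Means and standard deviations of soil CO2 (µmol m-2 s-1) and CH4
#' (nmol m-2 s-1) fluxes per drought period and topographic zone,
#' anchored on the published 2015 drought values: slope CO2
#' 3.79 ± 2.92 rising to 6.06 ± 4.26 (a 60% increase) with a 163%
#' increase in valleys; valley CH4 emission collapsing from 17.43 ± 29.60
#' to 1.67 ± 4.09, the ridge CH4 sink deepening by 76% (to -1.13), and
#' post-drought CH4 rebounds of 10.12 ± 7.84 (ridge) and 15.16 ± 7.03
#' (slope, a hundredfold increase on 0.15 ± 0.69 pre-drought). Cells the
#' source record does not report (all recovery-period means, ridge and
#' valley pre-drought CO2) are interpolated/reconstructed and flagged in
#' the `basis` column. `hot_weight` and `hot_mult` parameterize the
#' lognormal hot-moment mixture component of CH4 (the printed valley CH4
#' s.d. far exceeds its mean, implying strong right skew).
#'
#' @return data.frame with columns `period`, `zone`, `gas`, `mean`, `sd`,
#'   `hot_weight`, `hot_mult`, `basis`.
#' @export
default_flux_regimes <- function() {
  g <- function(period, zone, gas, mean, sd, hot_weight = 0,
                hot_mult = 0, basis = "published") {
    data.frame(period = period, zone = zone, gas = gas, mean = mean,
               sd = sd, hot_weight = hot_weight, hot_mult = hot_mult,
               basis = basis)
  }
  out <- rbind(
    # CO2, µmol m-2 s-1
    g("pre_drought",  "ridge",  "CO2", 2.10, 1.60, basis = "invented"),
    g("drought",      "ridge",  "CO2", 2.95, 2.20, basis = "invented"),
    g("recovery",     "ridge",  "CO2", 2.80, 2.10, basis = "interpolated"),
    g("post_drought", "ridge",  "CO2", 2.85, 2.10, basis = "invented"),
    g("pre_drought",  "slope",  "CO2", 3.79, 2.92),
    g("drought",      "slope",  "CO2", 6.06, 4.26),
    g("recovery",     "slope",  "CO2", 5.40, 3.80, basis = "interpolated"),
    g("post_drought", "slope",  "CO2", 5.70, 3.90, basis = "invented"),
    g("pre_drought",  "valley", "CO2", 2.50, 2.00, basis = "invented"),
    g("drought",      "valley", "CO2", 6.58, 4.40, basis = "reconstructed"),
    g("recovery",     "valley", "CO2", 5.20, 3.60, basis = "interpolated"),
    g("post_drought", "valley", "CO2", 5.50, 3.70, basis = "invented"),
    # CH4, nmol m-2 s-1
    g("pre_drought",  "ridge",  "CH4", -0.64, 0.76),
    g("drought",      "ridge",  "CH4", -1.13, 1.00, basis = "reconstructed"),
    g("recovery",     "ridge",  "CH4", -0.90, 0.90, basis = "interpolated"),
    g("post_drought", "ridge",  "CH4", 10.12, 7.84,
      hot_weight = 0.04, hot_mult = 4),
    g("pre_drought",  "slope",  "CH4", 0.15, 0.69),
    g("drought",      "slope",  "CH4", -1.93, 1.73),
    g("recovery",     "slope",  "CH4", -1.20, 1.20, basis = "interpolated"),
    g("post_drought", "slope",  "CH4", 15.16, 7.03,
      hot_weight = 0.04, hot_mult = 4),
    g("pre_drought",  "valley", "CH4", 17.43, 29.60,
      hot_weight = 0.05, hot_mult = 4),
    g("drought",      "valley", "CH4", 1.67, 4.09,
      hot_weight = 0.02, hot_mult = 4),
    g("recovery",     "valley", "CH4", 1.80, 4.00,
      hot_weight = 0.02, hot_mult = 4, basis = "interpolated"),
    g("post_drought", "valley", "CH4", 16.00, 25.00,
      hot_weight = 0.05, hot_mult = 4, basis = "invented"))
  rownames(out) <- NULL
  out
}

flux_regime_cell <- function(flux_regimes, period, zone, gas) {
  row <- flux_regimes[flux_regimes$period == period &
                      flux_regimes$zone == zone &
                      flux_regimes$gas == gas, ]
  if (nrow(row) != 1L)
    stop("no flux regime for cell (", period, ", ", zone, ", ", gas, ")",
         call. = FALSE)
  row
}

# Gaussian bulk with probability (1 - w); with probability w a hot moment:
# mean + sd * hot_mult * Lognormal(0, 0.75). Keeps heavy right tails
# without affecting the bulk location.
draw_flux <- function(n, cell) {
  if (cell$sd < 0) stop("flux regime s.d. must be >= 0", call. = FALSE)
  if (cell$hot_weight >= 0.5)
    stop("hot-moment weight must be < 0.5", call. = FALSE)
  x <- stats::rnorm(n, cell$mean, cell$sd)
  if (cell$hot_weight > 0) {
    hot <- stats::runif(n) < cell$hot_weight
    nh <- sum(hot)
    if (nh > 0)
      x[hot] <- cell$mean +
        cell$sd * cell$hot_mult * stats::rlnorm(nh, 0, 0.75)
  }
  x
}

#' Chamber malfunction probabilities
#'
#' @param p_short,p_long Probability a closure runs short (< 9 min) or
#'   long (> 11 min).
#' @param p_failed_flush Probability the pre-closure flush fails, leaving
#'   an initial concentration offset from ambient.
#' @param p_bad_covariate Probability of an anomalous temperature /
#'   humidity / pressure reading during the closure.
#' @param p_outage_day Probability an entire day of a chamber's record is
#'   lost to instrument outage.
#' @return Object of class `malfunction_spec`.
#' @export
malfunction_spec <- function(p_short = 0, p_long = 0, p_failed_flush = 0,
                             p_bad_covariate = 0, p_outage_day = 0) {
  p <- c(p_short, p_long, p_failed_flush, p_bad_covariate, p_outage_day)
  if (any(p < 0 | p > 1))
    stop("malfunction probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(p_short = p_short, p_long = p_long,
                 p_failed_flush = p_failed_flush,
                 p_bad_covariate = p_bad_covariate,
                 p_outage_day = p_outage_day),
            class = "malfunction_spec")
}

#' Chamber geometry
#'
#' Defaults match an automated soil chamber of 29.51 L headspace over a
#' 0.1824 m2 collar.
#'
#' @param volume_m3 Headspace volume.
#' @param area_m2 Basal area.
#' @return Named list.
#' @export
chamber_geometry <- function(volume_m3 = 0.02951, area_m2 = 0.1824) {
  if (volume_m3 <= 0 || area_m2 <= 0)
    stop("chamber volume and area must be positive", call. = FALSE)
  list(volume_m3 = volume_m3, area_m2 = area_m2)
}

#' Generate synthetic chamber closures with known true fluxes
#'
#' For each chamber (3 per zone by default) and each sampled day, draws
#' true CO2 and CH4 fluxes from the period x zone mixture of
#' `flux_regimes`, inverts them through the chamber concentration model
#' (linear accumulation, or the saturating exponential with rate `k_s`),
#' adds analyzer noise, and optionally injects malfunctions that the QC
#' stage is expected to catch. Every closure's true fluxes and injected
#' malfunctions are recorded in the returned truth table.
#'
#' @param config A [catena_config()]; `config$seed + 2` seeds the draws.
#' @param flux_regimes Flux regime table ([default_flux_regimes()]).
#' @param malfunctions A [malfunction_spec()].
#' @param geometry A [chamber_geometry()].
#' @param dates Days on which closures occur (default: every day of the
#'   trace record implied by `config`, which can be large; tests pass a
#'   short vector).
#' @param chambers_per_zone Chambers per topographic zone (default 3).
#' @param closures_per_day Closures per chamber per day (max 12).
#' @param sample_interval_s Analyzer sampling interval within a closure.
#' @param trace_model `"linear"` or `"exponential"` concentration path.
#' @param k_s Saturation rate constant for the exponential path (s-1).
#' @param noise_sd Named analyzer noise sd, ppm for CO2 / ppb for CH4.
#' @param ambient Named ambient concentrations (ppm CO2, ppb CH4).
#' @return List with `traces` (list of [chamber_trace()]) and `truth`
#'   (data.frame: `closure_id`, `chamber_id`, `zone`, `date`, `period`,
#'   `true_co2`, `true_ch4`, `malfunction`).
#' @export
generate_chamber_traces <- function(config,
                                    flux_regimes = default_flux_regimes(),
                                    malfunctions = malfunction_spec(),
                                    geometry = chamber_geometry(),
                                    dates = NULL,
                                    chambers_per_zone = 3L,
                                    closures_per_day = 12L,
                                    sample_interval_s = 15,
                                    trace_model = c("linear", "exponential"),
                                    k_s = 8e-4,
                                    noise_sd = c(CO2 = 0.5, CH4 = 2),
                                    ambient = c(CO2 = 400, CH4 = 1900)) {
  trace_model <- match.arg(trace_model)
  stopifnot(closures_per_day >= 1L, closures_per_day <= 12L)
  if (is.null(dates))
    dates <- seq(config$start_date, config$end_date, by = "day")
  dates <- as.Date(dates)
  zones <- c("ridge", "slope", "valley")
  chambers <- data.frame(
    chamber_id = paste0("ch_", rep(zones, each = chambers_per_zone), "_",
                        rep(seq_len(chambers_per_zone), times = 3L)),
    zone = rep(zones, each = chambers_per_zone))
  # fail fast if any needed regime cell is missing
  for (p in unique(as.character(assign_period(dates,
                                              config$breakpoint_dates))))
    for (z in zones) for (g in c("CO2", "CH4"))
      flux_regime_cell(flux_regimes, p, z, g)

  set.seed(config$seed + 2L)
  traces <- list()
  truth <- list()
  id <- 0L
  for (ci in seq_len(nrow(chambers))) {
    ch <- chambers$chamber_id[ci]; zone <- chambers$zone[ci]
    for (d in seq_along(dates)) {
      if (stats::runif(1) < malfunctions$p_outage_day) next
      day <- dates[d]
      period <- as.character(assign_period(day, config$breakpoint_dates))
      co2_cell <- flux_regime_cell(flux_regimes, period, zone, "CO2")
      ch4_cell <- flux_regime_cell(flux_regimes, period, zone, "CH4")
      for (cl in seq_len(closures_per_day)) {
        id <- id + 1L
        true_co2 <- draw_flux(1L, co2_cell)
        while (true_co2 <= 0) true_co2 <- draw_flux(1L, co2_cell)
        true_ch4 <- draw_flux(1L, ch4_cell)
        mal <- character(0)
        dur <- 600
        if (stats::runif(1) < malfunctions$p_short) {
          dur <- stats::runif(1, 360, 520); mal <- c(mal, "short")
        } else if (stats::runif(1) < malfunctions$p_long) {
          dur <- stats::runif(1, 680, 900); mal <- c(mal, "long")
        }
        temp_c <- stats::rnorm(1, 24, 1)
        rh <- stats::runif(1, 85, 99)
        press <- stats::rnorm(1, 101.3, 0.3)
        if (stats::runif(1) < malfunctions$p_bad_covariate) {
          temp_c <- 60; mal <- c(mal, "bad_covariate")
        }
        c0 <- ambient
        if (stats::runif(1) < malfunctions$p_failed_flush) {
          c0 <- ambient * (1 + sample(c(-1, 1), 2L, replace = TRUE) *
                             stats::runif(2L, 0.3, 0.6))
          mal <- c(mal, "failed_flush")
        }
        t_s <- seq(0, dur, by = sample_interval_s)
        conc <- function(gas, true_flux) {
          slope <- flux_to_concentration_rate(
            true_flux, temp_c, press, geometry$volume_m3, geometry$area_m2)
          path <- if (trace_model == "linear") c0[[gas]] + slope * t_s
                  else (c0[[gas]] + slope / k_s) -
                       (slope / k_s) * exp(-k_s * t_s)
          path + stats::rnorm(length(t_s), 0, noise_sd[[gas]])
        }
        start <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC") +
          (cl - 1L) * 7200
        traces[[id]] <- chamber_trace(
          chamber_id = ch, zone = zone, closure_start = start,
          samples = data.frame(t_s = t_s,
                               co2_ppm = conc("CO2", true_co2),
                               ch4_ppb = conc("CH4", true_ch4)),
          temp_c = temp_c, rh_pct = rh, press_kpa = press,
          volume_m3 = geometry$volume_m3, area_m2 = geometry$area_m2,
          ambient = ambient, duration_s = dur)
        truth[[id]] <- data.frame(
          closure_id = id, chamber_id = ch, zone = zone, date = day,
          period = period, true_co2 = true_co2, true_ch4 = true_ch4,
          malfunction = paste(mal, collapse = ";"))
      }
    }
  }
  truth <- do.call(rbind, truth)
  if (!is.null(truth)) rownames(truth) <- NULL
  list(traces = traces[!vapply(traces, is.null, logical(1))],
       truth = truth)
}

#' Draw a flux observation table directly from the regime mixtures
#'
#' Bypasses the chamber model: draws retained-flux observations (one per
#' chamber, day and gas) straight from the period x zone mixture. Used
#' for statistical power / calibration simulations where the chamber
#' forward model is irrelevant. CO2 draws are resampled to be positive
#' (soil respiration cannot be negative and the downstream analysis log
#' transforms CO2).
#'
#' @param config A [catena_config()].
#' @param flux_regimes Flux regime table.
#' @param days_per_period Sampled days within each drought period.
#' @param chambers_per_zone Chambers per zone.
#' @param seed Seed (default `config$seed + 3`).
#' @return data.frame: `chamber_id`, `zone`, `period`, `day`, `gas`,
#'   `flux`.
#' @export
generate_flux_table <- function(config,
                                flux_regimes = default_flux_regimes(),
                                days_per_period = 15L,
                                chambers_per_zone = 3L,
                                seed = config$seed + 3L) {
  set.seed(seed)
  zones <- c("ridge", "slope", "valley")
  grid <- expand.grid(
    chamber = seq_len(chambers_per_zone), zone = zones,
    period = drought_periods(), day = seq_len(days_per_period),
    gas = c("CO2", "CH4"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$chamber_id <- paste0("ch_", grid$zone, "_", grid$chamber)
  grid$flux <- NA_real_
  for (p in unique(grid$period)) for (z in zones)
    for (g in c("CO2", "CH4")) {
      cell <- flux_regime_cell(flux_regimes, p, z, g)
      w <- grid$period == p & grid$zone == z & grid$gas == g
      x <- draw_flux(sum(w), cell)
      if (g == "CO2") {
        for (i in which(x <= 0)) {
          while (x[i] <= 0) x[i] <- draw_flux(1L, cell)
        }
      }
      grid$flux[w] <- x
    }
  grid[, c("chamber_id", "zone", "period", "day", "gas", "flux")]
}
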