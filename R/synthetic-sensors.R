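# Synthetic hourly soil-sensor records (moisture, O2, temperature) for a
# ridge-slope-valley catena, with piecewise regimes around known breakpoint
# dates so that segmentation can be tested against ground truth.

#' Default sensor regime table
#'
#' One row per drought period x topographic position with the moments of
#' the stationary process simulated within that regime. Moisture and O2
#' means are linearly graded from the ridge endpoint to the valley
#' endpoint; endpoints for the pre-drought and drought periods are the
#' published zone means of the 2015 Caribbean drought record (ridge
#' moisture 0.36 -> 0.13 v/v; valley 0.51 -> 0.37 v/v; valley O2 5.6 ->
#' 11.2 %). Recovery-period values are interpolations (no published
#' values exist) and are flagged as such in generator truth metadata;
#' post-drought moisture returns to pre-drought levels.
#'
#' @param config A [catena_config()].
#' @return data.frame with columns `period`, `position`, `moisture_mean`,
#'   `moisture_sd`, `o2_mean`, `o2_sd`, `temp_mean`, `temp_amplitude`,
#'   `temp_sd`, `ar1`.
#' @export
default_sensor_regimes <- function(config = catena_config()) {
  periods <- drought_periods()
  # ridge / valley endpoints per period: moisture (v/v), O2 (%)
  moist_ridge <- c(pre_drought = 0.36, drought = 0.13,
                   recovery = 0.25, post_drought = 0.36)
  moist_valley <- c(pre_drought = 0.51, drought = 0.37,
                    recovery = 0.42, post_drought = 0.51)
  msd_ridge <- c(pre_drought = 0.08, drought = 0.02,
                 recovery = 0.05, post_drought = 0.06)
  msd_valley <- c(pre_drought = 0.01, drought = 0.07,
                  recovery = 0.05, post_drought = 0.03)
  o2_ridge <- c(pre_drought = 20.5, drought = 20.8,
                recovery = 20.6, post_drought = 20.5)
  o2_valley <- c(pre_drought = 5.6, drought = 11.2,
                 recovery = 8.0, post_drought = 6.5)
  o2sd_ridge <- c(pre_drought = 0.5, drought = 0.4,
                  recovery = 0.5, post_drought = 0.5)
  o2sd_valley <- c(pre_drought = 4.1, drought = 3.4,
                   recovery = 3.8, post_drought = 4.0)
  frac <- (seq_len(config$n_positions) - 1) / (config$n_positions - 1)
  out <- expand.grid(period = periods,
                     position = seq_len(config$n_positions),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  f <- frac[out$position]
  p <- out$period
  out$moisture_mean <- (1 - f) * moist_ridge[p] + f * moist_valley[p]
  out$moisture_sd <- (1 - f) * msd_ridge[p] + f * msd_valley[p]
  out$o2_mean <- (1 - f) * o2_ridge[p] + f * o2_valley[p]
  out$o2_sd <- (1 - f) * o2sd_ridge[p] + f * o2sd_valley[p]
  out$temp_mean <- 23
  out$temp_amplitude <- 2.5
  out$temp_sd <- 0.4
  out$ar1 <- 0.9
  # recovery is a trending regime: gradual rewetting from the drought
  # level toward post-drought moisture across the whole period
  out$ramp <- ifelse(out$period == "recovery", "from_previous", "none")
  out
}

# marginal-sd-preserving AR(1) noise of length n
ar1_noise <- function(n, sd, phi) {
  if (sd <= 0) return(numeric(n))
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
  innov[1L] <- stats::rnorm(1L, sd = sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# Regime mean path: flat periods sit at their period mean; a period with
# ramp = "from_previous" runs linearly from the previous period's end
# value to the reflection `2 * mean - prev_end`, so its period average
# equals the configured mean. Level discontinuities at breakpoints are
# then smoothed linearly over a window of `ramp_days` centred on the
# breakpoint (centring keeps within-period sample means close to the
# configured means). `tdays` is days since series start.
regime_mean_path <- function(tdays, period_means, bp_days, ramp_days,
                             ramp = NULL) {
  np <- length(period_means)
  if (is.null(ramp)) ramp <- rep("none", np)
  if (ramp[1L] == "from_previous")
    stop("the first period cannot ramp from a previous one",
         call. = FALSE)
  bounds <- c(min(tdays), bp_days, max(tdays) + 1e-9)
  idx <- findInterval(tdays, bp_days) + 1L
  path <- numeric(length(tdays))
  prev_end <- period_means[1L]
  for (p in seq_len(np)) {
    w <- idx == p
    if (ramp[p] == "from_previous") {
      e <- 2 * period_means[p] - prev_end
      frac <- (tdays[w] - bounds[p]) / (bounds[p + 1L] - bounds[p])
      path[w] <- prev_end + (e - prev_end) * frac
      prev_end <- e
    } else {
      path[w] <- period_means[p]
      prev_end <- period_means[p]
    }
  }
  if (ramp_days > 0) {
    half <- ramp_days / 2
    for (b in bp_days) {
      lo <- b - half; hi <- b + half
      w <- tdays >= lo & tdays < hi
      if (any(w)) {
        i_lo <- which.min(abs(tdays - lo)); i_hi <- which.min(abs(tdays - hi))
        path[w] <- path[i_lo] +
          (path[i_hi] - path[i_lo]) * (tdays[w] - lo) / (hi - lo)
      }
    }
  }
  path
}

#' Generate an hourly synthetic soil-sensor record
#'
#' Simulates hourly volumetric moisture, soil O2 and soil temperature for
#' every transect x position of the catena. Within each drought period a
#' sensor's series is stationary AR(1) noise around its regime mean, with
#' linear ramps (width `config$transition_days`) joining consecutive
#' regime means across each breakpoint; regimes flagged
#' `ramp = "from_previous"` in the regime table (by default, the
#' recovery period's gradual rewetting) instead trend linearly across
#' the whole period. Soil moisture additionally carries a catena-shared
#' daily component (`shared_sd`, `shared_ar1`) representing rain-event
#' forcing common to all sensors; without it, averaging many independent
#' sensors would produce an unrealistically smooth catena-mean series.
#' Day-to-day rain forcing is taken as white (`shared_ar1 = 0`): daily
#' rainfall totals carry little day-scale memory, and sub-daily
#' persistence already lives in the hourly per-sensor AR(1).
#' Temperature follows a sinusoidal annual cycle peaking in early
#' August.
#'
#' @param config A [catena_config()]; `config$seed` seeds the simulation.
#' @param regimes Regime table as from [default_sensor_regimes()]; must
#'   contain every period x position cell.
#' @param shared_sd Marginal sd (v/v) of the shared daily moisture
#'   component (default 0.03; 0 disables it).
#' @param shared_ar1 AR(1) coefficient of the shared component
#'   (default 0, i.e. white day-to-day forcing).
#' @return A list with elements
#'   \describe{
#'     \item{sensors}{data.frame: `timestamp` (UTC), `date`, `transect`,
#'       `position`, `zone`, `moisture`, `o2_pct`, `temp_c`.}
#'     \item{truth}{list with the true `breakpoint_dates`, the `regimes`
#'       table, noise settings, and `interpolated_periods` flagging
#'       regime rows that are interpolations rather than published
#'       values.}
#'   }
#' @export
#' @examples
#' cfg <- catena_config(end_date = as.Date("2015-02-01"),
#'                      breakpoint_dates = as.Date(c("2014-11-20",
#'                        "2014-12-15", "2015-01-10")), seed = 7)
#' sim <- generate_sensor_series(cfg)
#' head(sim$sensors)
generate_sensor_series <- function(config,
                                   regimes = default_sensor_regimes(config),
                                   shared_sd = 0.03,
                                   shared_ar1 = 0) {
  periods <- drought_periods()
  need <- expand.grid(period = periods,
                      position = seq_len(config$n_positions),
                      stringsAsFactors = FALSE)
  key <- paste(regimes$period, regimes$position)
  miss <- !(paste(need$period, need$position) %in% key)
  if (any(miss)) {
    i <- which(miss)[1L]
    stop("regime table is missing cell (period=", need$period[i],
         ", position=", need$position[i], ")", call. = FALSE)
  }
  for (col in c("moisture_mean", "moisture_sd", "o2_mean", "o2_sd",
                "temp_mean", "temp_amplitude", "temp_sd", "ar1")) {
    if (!col %in% names(regimes) || any(!is.finite(regimes[[col]])))
      stop("regime table column `", col, "` missing or non-finite",
           call. = FALSE)
  }

  set.seed(config$seed)
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(config$end_date, "00:00:00"), tz = "UTC")
  ts <- seq(t0, t1, by = "hour")
  nh <- length(ts)
  tdays <- as.numeric(difftime(ts, t0, units = "days"))
  bp_days <- as.numeric(config$breakpoint_dates - config$start_date)
  doy <- as.POSIXlt(ts)$yday + 1L

  n_days <- ceiling(max(tdays)) + 1L
  shared_daily <- ar1_noise(n_days, shared_sd, shared_ar1)
  shared_hourly <- shared_daily[floor(tdays) + 1L]

  out <- vector("list", config$n_transects * config$n_positions)
  k <- 0L
  for (tr in seq_len(config$n_transects)) {
    for (pos in seq_len(config$n_positions)) {
      reg <- regimes[regimes$position == pos, ]
      reg <- reg[match(periods, reg$period), ]
      ramp <- if ("ramp" %in% names(reg)) reg$ramp else NULL
      m_path <- regime_mean_path(tdays, reg$moisture_mean, bp_days,
                                 config$transition_days, ramp)
      o_path <- regime_mean_path(tdays, reg$o2_mean, bp_days,
                                 config$transition_days, ramp)
      # per-period marginal sd, interpolated the same way as the means
      m_sd <- regime_mean_path(tdays, reg$moisture_sd, bp_days,
                               config$transition_days)
      o_sd <- regime_mean_path(tdays, reg$o2_sd, bp_days,
                               config$transition_days)
      phi <- reg$ar1[1L]
      moisture <- m_path + shared_hourly +
        ar1_noise(nh, 1, phi) * m_sd
      o2 <- o_path + ar1_noise(nh, 1, phi) * o_sd
      temp <- reg$temp_mean[1L] +
        reg$temp_amplitude[1L] * cos(2 * pi * (doy - 213) / 365.25) +
        ar1_noise(nh, reg$temp_sd[1L], phi)
      k <- k + 1L
      out[[k]] <- data.frame(
        timestamp = ts,
        date = as.Date(floor(tdays), origin = config$start_date),
        transect = tr,
        position = pos,
        zone = unname(config$zone_map[pos]),
        moisture = pmin(pmax(moisture, 0.005), 0.995),
        o2_pct = pmin(pmax(o2, 0), 20.95),
        temp_c = temp)
    }
  }
  sensors <- do.call(rbind, out)
  rownames(sensors) <- NULL
  truth <- list(
    breakpoint_dates = config$breakpoint_dates,
    regimes = regimes,
    shared_sd = shared_sd,
    shared_ar1 = shared_ar1,
    transition_days = config$transition_days,
    interpolated_periods = "recovery",
    seed = config$seed)
  list(sensors = sensors, truth = truth)
}

#' Daily catena-mean soil moisture
#'
#' Averages soil moisture over all sensors per calendar day; the series
#' that drought-period segmentation operates on.
#'
#' @param sensors Sensor data.frame as from [generate_sensor_series()].
#' @return data.frame with columns `date`, `moisture`.
#' @export
daily_catena_moisture <- function(sensors) {
  stopifnot(all(c("date", "moisture") %in% names(sensors)))
  agg <- stats::aggregate(moisture ~ date, data = sensors, FUN = mean)
  agg[order(agg$date), , drop = FALSE]
}
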