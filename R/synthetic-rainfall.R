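# Synthetic daily rainfall: a drought year plus a multi-year baseline
# climatology, with annual totals pinned exactly to configured targets.

#' Generate a synthetic daily rainfall record with baseline climatology
#'
#' Produces a drought-year daily rainfall series plus `baseline_years`
#' synthetic preceding years. Wet days occur with probability
#' `wet_day_prob`; wet-day amounts are gamma-distributed and then rescaled
#' so each year's total equals its target exactly (the drought year hits
#' `drought_annual_mm`, each baseline year `baseline_annual_mm`). The
#' defaults reproduce the 2015 El Verde situation: 2035 mm against a
#' 4219 mm decadal baseline, a 48% decline.
#'
#' @param config A [catena_config()]; the drought year is the calendar
#'   year of the first breakpoint.
#' @param baseline_annual_mm Target annual total for each baseline year
#'   (default 4219).
#' @param drought_annual_mm Target drought-year total (default 2035).
#' @param baseline_years Number of synthetic baseline years (default 10,
#'   the minimum supported).
#' @param wet_day_prob Daily probability of measurable rain.
#' @return List with elements
#'   \describe{
#'     \item{rainfall}{data.frame `date`, `rain_mm`, `year_type`
#'       (`"baseline"`/`"drought"`) covering all years.}
#'     \item{climatology}{data.frame `doy`, `mean_mm`: baseline mean
#'       rainfall per day-of-year.}
#'     \item{truth}{target totals and seed.}
#'   }
#' @export
#' @examples
#' rf <- generate_rainfall(catena_config(seed = 3))
#' tapply(rf$rainfall$rain_mm, format(rf$rainfall$date, "%Y"), sum)
generate_rainfall <- function(config,
                              baseline_annual_mm = 4219,
                              drought_annual_mm = 2035,
                              baseline_years = 10L,
                              wet_day_prob = 0.75) {
  if (baseline_annual_mm <= 0 || drought_annual_mm <= 0)
    stop("annual rainfall totals must be positive", call. = FALSE)
  if (baseline_years < 10L)
    stop("baseline must span at least 10 years", call. = FALSE)
  set.seed(config$seed + 1L)
  drought_year <- as.integer(format(config$breakpoint_dates[1L], "%Y"))
  years <- c((drought_year - baseline_years):(drought_year - 1L),
             drought_year)
  one_year <- function(year, total) {
    dates <- seq(as.Date(paste0(year, "-01-01")),
                 as.Date(paste0(year, "-12-31")), by = "day")
    n <- length(dates)
    wet <- stats::runif(n) < wet_day_prob
    amt <- numeric(n)
    amt[wet] <- stats::rgamma(sum(wet), shape = 0.9, scale = 18)
    if (sum(amt) > 0) amt <- amt * (total / sum(amt))
    data.frame(date = dates, rain_mm = amt,
               year_type = if (year == drought_year) "drought"
                           else "baseline")
  }
  tabs <- lapply(years, function(y)
    one_year(y, if (y == drought_year) drought_annual_mm
                else baseline_annual_mm))
  rainfall <- do.call(rbind, tabs)
  rownames(rainfall) <- NULL
  base <- rainfall[rainfall$year_type == "baseline", ]
  doy <- as.integer(format(base$date, "%j"))
  clim <- stats::aggregate(list(mean_mm = base$rain_mm),
                           by = list(doy = doy), FUN = mean)
  list(rainfall = rainfall,
       climatology = clim[order(clim$doy), ],
       truth = list(baseline_annual_mm = baseline_annual_mm,
                    drought_annual_mm = drought_annual_mm,
                    drought_year = drought_year,
                    seed = config$seed))
}

#' Daily rainfall anomaly against the baseline climatology
#'
#' @param rainfall data.frame from [generate_rainfall()] (or a real record
#'   with the same columns).
#' @param climatology Baseline day-of-year climatology
#'   (`doy`, `mean_mm`).
#' @return data.frame `date`, `rain_mm`, `anomaly_mm` restricted to the
#'   drought year.
#' @export
rainfall_anomaly <- function(rainfall, climatology) {
  dr <- rainfall[rainfall$year_type == "drought", , drop = FALSE]
  doy <- as.integer(format(dr$date, "%j"))
  dr$anomaly_mm <- dr$rain_mm -
    climatology$mean_mm[match(doy, climatology$doy)]
  dr
}
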