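#' Study configuration for a ridge-slope-valley catena
#'
#' Describes the sensor array layout and the drought-period calendar used
#' throughout the package: replicate transects of topographic positions
#' (1 = ridge crest ... `n_positions` = valley bottom), the observation
#' window, and the three moisture-regime breakpoint dates that split the
#' record into four drought periods (pre-drought, drought, recovery,
#' post-drought).
#'
#' @param n_transects Number of replicate downslope transects (default 5).
#' @param n_positions Topographic positions per transect, ridge to valley
#'   (default 7).
#' @param zone_map Character vector of length `n_positions` assigning each
#'   position to one of `"ridge"`, `"slope"`, `"valley"`. Defaults to
#'   position 1 = ridge, interior positions = slope, last position = valley.
#' @param start_date,end_date Observation window (`Date`).
#' @param breakpoint_dates Three strictly increasing `Date`s inside
#'   `(start_date, end_date)` separating the four drought periods.
#'   Defaults are the moisture-regime shifts of the 2015 Caribbean drought.
#' @param transition_days Width in days of the linear ramp between regime
#'   means, centred on each breakpoint (default 14).
#' @param seed Integer seed driving every stochastic generator that takes
#'   this config.
#'
#' @return An object of class `catena_config` (a list).
#' @export
#' @examples
#' cfg <- catena_config(seed = 42)
#' cfg$breakpoint_dates
catena_config <- function(n_transects = 5L,
                          n_positions = 7L,
                          zone_map = NULL,
                          start_date = as.Date("2014-11-01"),
                          end_date = as.Date("2016-02-01"),
                          breakpoint_dates = as.Date(c("2015-04-25",
                                                       "2015-08-24",
                                                       "2015-11-24")),
                          transition_days = 14,
                          seed = 1L) {
  n_transects <- as.integer(n_transects)
  n_positions <- as.integer(n_positions)
  stopifnot(n_transects >= 1L, n_positions >= 2L)
  if (is.null(zone_map)) zone_map <- default_zone_map(n_positions)
  if (length(zone_map) != n_positions)
    stop("`zone_map` must assign a zone to each of the ", n_positions,
         " positions", call. = FALSE)
  bad <- setdiff(unique(zone_map), c("ridge", "slope", "valley"))
  if (length(bad))
    stop("unknown zone label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  breakpoint_dates <- as.Date(breakpoint_dates)
  if (length(breakpoint_dates) != 3L ||
      any(diff(as.numeric(breakpoint_dates)) <= 0))
    stop("`breakpoint_dates` must be three strictly increasing dates",
         call. = FALSE)
  if (breakpoint_dates[1L] <= start_date || breakpoint_dates[3L] >= end_date)
    stop("`breakpoint_dates` must lie strictly inside (start_date, end_date)",
         call. = FALSE)
  structure(
    list(n_transects = n_transects,
         n_positions = n_positions,
         zone_map = stats::setNames(zone_map, seq_len(n_positions)),
         start_date = start_date,
         end_date = end_date,
         breakpoint_dates = breakpoint_dates,
         transition_days = transition_days,
         seed = as.integer(seed)),
    class = "catena_config")
}

#' @export
print.catena_config <- function(x, ...) {
  cat("Catena study configuration\n")
  cat("  transects x positions:", x$n_transects, "x", x$n_positions, "\n")
  cat("  window:", format(x$start_date), "to", format(x$end_date), "\n")
  cat("  breakpoints:", paste(format(x$breakpoint_dates), collapse = ", "),
      "\n")
  invisible(x)
}

#' Default position-to-zone assignment
#'
#' Position 1 is the ridge crest, the final position the valley bottom,
#' everything between a slope position.
#'
#' @param n_positions Number of positions.
#' @return Character vector of zone labels.
#' @export
default_zone_map <- function(n_positions = 7L) {
  c("ridge", rep("slope", n_positions - 2L), "valley")
}

#' Drought-period labels in temporal order
#'
#' @return `c("pre_drought", "drought", "recovery", "post_drought")`
#' @export
drought_periods <- function() {
  c("pre_drought", "drought", "recovery", "post_drought")
}

#' Assign drought-period labels to dates
#'
#' A breakpoint date is the first day of the period it opens, i.e. periods
#' are the half-open intervals `[start, bp1)`, `[bp1, bp2)`, `[bp2, bp3)`,
#' `[bp3, end]`.
#'
#' @param dates `Date` vector.
#' @param breakpoint_dates Three increasing `Date`s.
#' @return Ordered factor with levels [drought_periods()].
#' @export
#' @examples
#' assign_period(as.Date(c("2015-03-01", "2015-06-01")),
#'               as.Date(c("2015-04-25", "2015-08-24", "2015-11-24")))
assign_period <- function(dates, breakpoint_dates) {
  dates <- as.Date(dates)
  breakpoint_dates <- as.Date(breakpoint_dates)
  stopifnot(length(breakpoint_dates) == 3L)
  idx <- findInterval(as.numeric(dates), as.numeric(breakpoint_dates)) + 1L
  factor(drought_periods()[idx], levels = drought_periods(), ordered = TRUE)
}
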