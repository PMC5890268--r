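# Shared fixtures: analytic chamber traces and an independent
# exhaustive-search segmentation oracle.

ambient_default <- c(CO2 = 400, CH4 = 1900)

# trace whose concentration path is supplied as a function of t (seconds)
make_trace <- function(co2_fun = function(t) 400 + 0 * t,
                       ch4_fun = function(t) 1900 + 0 * t,
                       duration_s = 600, dt = 15,
                       temp_c = 25, rh_pct = 90, press_kpa = 101.325,
                       volume_m3 = 0.02951, area_m2 = 0.1824,
                       ambient = ambient_default, zone = "slope") {
  t <- seq(0, duration_s, by = dt)
  chamber_trace("ch_test", zone, as.POSIXct("2015-03-01", tz = "UTC"),
                data.frame(t_s = t, co2_ppm = co2_fun(t),
                           ch4_ppb = ch4_fun(t)),
                temp_c = temp_c, rh_pct = rh_pct, press_kpa = press_kpa,
                volume_m3 = volume_m3, area_m2 = area_m2,
                ambient = ambient, duration_s = duration_s)
}

# ppm/s concentration slope produced by a surface flux in field units
slope_for_flux <- function(flux, temp_c = 25, press_kpa = 101.325,
                           volume_m3 = 0.02951, area_m2 = 0.1824) {
  flux * 8.314462618 * (temp_c + 273.15) * area_m2 /
    (press_kpa * 1000 * volume_m3)
}

# independent exhaustive-search segmentation oracle: enumerates every
# admissible breakpoint set and scores segments with lm residuals
brute_force_breaks <- function(y, n_breaks, h) {
  n <- length(y)
  min_len <- max(ceiling(h * n), 3L)
  seg_rss <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1L < min_len) next
    t <- i:j
    seg_rss[i, j] <- sum(stats::lm(y[i:j] ~ t)$residuals^2)
  }
  if (n_breaks == 0L)
    return(list(breakpoints = integer(0), rss = seg_rss[1L, n]))
  best <- list(rss = Inf, breakpoints = integer(0))
  cand <- utils::combn(seq_len(n - 1L), n_breaks)
  for (col in seq_len(ncol(cand))) {
    bp <- cand[, col]
    bounds <- c(0L, bp, n)
    lens <- diff(bounds)
    if (any(lens < min_len)) next
    tot <- sum(vapply(seq_len(length(bounds) - 1L), function(s)
      seg_rss[bounds[s] + 1L, bounds[s + 1L]], numeric(1)))
    if (tot < best$rss) best <- list(rss = tot, breakpoints = bp)
  }
  best
}

# small fully specified flux-summary table for upscaling tests
toy_summaries <- function(means, sds) {
  grid <- expand.grid(period = drought_periods(),
                      zone = c("ridge", "slope", "valley"),
                      gas = c("CO2", "CH4"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$mean <- means[seq_len(nrow(grid)) %% length(means) + 1L]
  grid$sd <- sds[seq_len(nrow(grid)) %% length(sds) + 1L]
  grid
}
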