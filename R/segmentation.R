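# Piecewise-linear segmentation of a soil-moisture series: globally
# optimal breakpoints by dynamic programming over a precomputed
# segment-RSS triangle, BIC selection of the breakpoint count, and a
# supF structural-change test with a simulated null.

#' Segmentation settings
#'
#' @param max_breaks Largest breakpoint count considered (default 4).
#' @param h Minimum segment length as a fraction of the series (default
#'   0.15, in (0, 0.5)).
#' @param n_null_sims Simulation replicates for the supF null
#'   distribution (default 999).
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(max_breaks = 4L, h = 0.15,
                                n_null_sims = 999L) {
  stopifnot(max_breaks >= 0L, h > 0, h < 0.5, n_null_sims >= 99L)
  structure(list(max_breaks = as.integer(max_breaks), h = h,
                 n_null_sims = as.integer(n_null_sims)),
            class = "segmentation_config")
}

min_segment_length <- function(n, h) max(ceiling(h * n), 3L)

# RSS of an intercept + trend OLS on every admissible segment [i, j].
# Returns an n x n matrix with rss[i, j] filled for j >= i + min_len - 1.
segment_rss_matrix <- function(y, min_len) {
  n <- length(y)
  t <- as.numeric(seq_len(n))
  cy <- cumsum(y); cyy <- cumsum(y * y)
  ct <- cumsum(t); ctt <- cumsum(t * t); cty <- cumsum(t * y)
  pre <- function(v, i) if (i > 1L) v[i - 1L] else 0
  rss <- matrix(NA_real_, n, n)
  for (i in seq_len(n - min_len + 1L)) {
    j <- (i + min_len - 1L):n
    m <- j - i + 1
    Sy <- cy[j] - pre(cy, i);   Syy <- cyy[j] - pre(cyy, i)
    St <- ct[j] - pre(ct, i);   Stt <- ctt[j] - pre(ctt, i)
    Sty <- cty[j] - pre(cty, i)
    den <- m * Stt - St * St
    b <- (m * Sty - St * Sy) / den
    a <- (Sy - b * St) / m
    rss[i, j] <- pmax(Syy - a * Sy - b * Sty, 0)
  }
  rss
}

segment_fit <- function(y, i, j) {
  t <- i:j
  f <- stats::lm.fit(cbind(1, t), y[i:j])
  list(intercept = unname(f$coefficients[1L]),
       slope = unname(f$coefficients[2L]),
       rss = sum(f$residuals^2), n = j - i + 1L)
}

#' Globally optimal breakpoints for a fixed breakpoint count
#'
#' Finds the `n_breaks` breakpoints minimizing the total residual sum of
#' squares of per-segment intercept+trend OLS fits, by dynamic
#' programming over the precomputed segment-RSS triangle (each segment at
#' least `ceiling(h * n)` points). Breakpoints are reported as the last
#' index of each segment but the final one.
#'
#' @param y Numeric series.
#' @param n_breaks Number of breakpoints.
#' @param config A [segmentation_config()].
#' @param rss Optional precomputed [segment_rss_matrix()] (internal
#'   reuse).
#' @return List: `breakpoints` (integer vector, empty when
#'   `n_breaks = 0`), `segments` (data.frame `start`, `end`, `intercept`,
#'   `slope`, `rss`, `n`), `rss` (total).
#' @export
optimal_breakpoints <- function(y, n_breaks, config = segmentation_config(),
                                rss = NULL) {
  n <- length(y)
  min_len <- min_segment_length(n, config$h)
  if (n < (n_breaks + 1L) * min_len)
    stop("series of length ", n, " cannot host ", n_breaks,
         " breakpoints with minimum segment length ", min_len,
         call. = FALSE)
  if (is.null(rss)) rss <- segment_rss_matrix(y, min_len)
  # cost[m + 1, j]: best RSS of fitting y[1..j] with m breakpoints
  cost <- matrix(Inf, n_breaks + 1L, n)
  from <- matrix(NA_integer_, n_breaks + 1L, n)
  cost[1L, ] <- rss[1L, ]
  if (n_breaks >= 1L) {
    for (m in seq_len(n_breaks)) {
      # last segment [i + 1, j]; prefix y[1..i] uses m - 1 breaks
      lo_i <- m * min_len
      for (j in ((m + 1L) * min_len):n) {
        i <- lo_i:(j - min_len)
        tot <- cost[m, i] + rss[i + 1L, j]
        w <- which.min(tot)
        cost[m + 1L, j] <- tot[w]
        from[m + 1L, j] <- i[w]
      }
    }
  }
  bps <- integer(0)
  j <- n
  if (n_breaks >= 1L) {
    for (m in seq(n_breaks + 1L, 2L)) {
      j <- from[m, j]
      bps <- c(j, bps)
    }
  }
  bounds <- c(0L, bps, n)
  segments <- do.call(rbind, lapply(seq_len(length(bounds) - 1L),
    function(s) {
      fit <- segment_fit(y, bounds[s] + 1L, bounds[s + 1L])
      data.frame(start = bounds[s] + 1L, end = bounds[s + 1L],
                 intercept = fit$intercept, slope = fit$slope,
                 rss = fit$rss, n = fit$n)
    }))
  list(breakpoints = bps, segments = segments, rss = sum(segments$rss))
}

segmentation_bic <- function(n, rss, n_breaks, k = 2L) {
  npar <- (n_breaks + 1L) * k + n_breaks + 1L
  n * log(rss / n) + npar * log(n)
}

#' Select the breakpoint count by BIC and segment the series
#'
#' Computes the optimal segmentation for every breakpoint count from 0 to
#' `config$max_breaks` (as far as the series length allows), scores each
#' with BIC — parameter count `(m + 1) * 2 + m + 1` for m breakpoints
#' (per-segment intercept and trend, the break positions, the error
#' variance) — and returns the BIC-minimizing segmentation together with
#' the supF structural-change test.
#'
#' @param y Numeric series (e.g. daily catena-mean moisture).
#' @param config A [segmentation_config()].
#' @param dates Optional `Date` vector parallel to `y`; breakpoint dates
#'   are then reported alongside indices.
#' @param run_sup_f Compute the supF test and p-value (default TRUE;
#'   costs `n_null_sims` null simulations).
#' @return Object of class `segmentation_result`: `breakpoints`,
#'   `breakpoint_dates` (if dates given), `segments`, `bic_table`
#'   (`n_breaks`, `rss`, `bic`), `chosen_n_breaks`, `sup_f`, `p_value`.
#' @export
select_n_breaks <- function(y, config = segmentation_config(),
                            dates = NULL, run_sup_f = TRUE) {
  n <- length(y)
  min_len <- min_segment_length(n, config$h)
  feasible <- 0:min(config$max_breaks, n %/% min_len - 1L)
  rss_mat <- segment_rss_matrix(y, min_len)
  fits <- lapply(feasible, function(m)
    optimal_breakpoints(y, m, config, rss = rss_mat))
  bic_table <- data.frame(
    n_breaks = feasible,
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    bic = vapply(seq_along(feasible), function(i)
      segmentation_bic(n, fits[[i]]$rss, feasible[i]), numeric(1)))
  best <- which.min(bic_table$bic)
  chosen <- fits[[best]]
  sf <- if (run_sup_f) sup_f_test(y, config) else
    list(statistic = NA_real_, p_value = NA_real_)
  structure(
    list(breakpoints = chosen$breakpoints,
         breakpoint_dates = if (!is.null(dates))
           as.Date(dates)[chosen$breakpoints] else NULL,
         segments = chosen$segments,
         bic_table = bic_table,
         chosen_n_breaks = bic_table$n_breaks[best],
         sup_f = sf$statistic,
         p_value = sf$p_value,
         n = n, config = config),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("Piecewise-linear segmentation (n =", x$n, ")\n")
  cat("  chosen breakpoints:", x$chosen_n_breaks, "\n")
  if (length(x$breakpoints))
    cat("  at index:", paste(x$breakpoints, collapse = ", "),
        if (!is.null(x$breakpoint_dates))
          paste0("(", paste(format(x$breakpoint_dates), collapse = ", "),
                 ")") else "", "\n")
  if (is.finite(x$sup_f))
    cat("  supF =", format(x$sup_f, digits = 4),
        ", p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

# supF statistic only (vectorized over candidate splits)
sup_f_stat <- function(y, min_len) {
  n <- length(y)
  t <- as.numeric(seq_len(n))
  cy <- cumsum(y); cyy <- cumsum(y * y)
  ct <- cumsum(t); ctt <- cumsum(t * t); cty <- cumsum(t * y)
  seg_rss <- function(i, j) {  # vectorized over equal-length i, j
    pre <- function(v, idx) ifelse(idx > 1L, v[pmax(idx - 1L, 1L)], 0)
    m <- j - i + 1
    Sy <- cy[j] - pre(cy, i);  Syy <- cyy[j] - pre(cyy, i)
    St <- ct[j] - pre(ct, i);  Stt <- ctt[j] - pre(ctt, i)
    Sty <- cty[j] - pre(cty, i)
    den <- m * Stt - St * St
    b <- (m * Sty - St * Sy) / den
    a <- (Sy - b * St) / m
    pmax(Syy - a * Sy - b * Sty, 0)
  }
  s <- min_len:(n - min_len)       # split: segments [1,s], [s+1,n]
  rss0 <- seg_rss(1L, n)
  rss1 <- seg_rss(rep(1L, length(s)), s) + seg_rss(s + 1L, rep(n, length(s)))
  k <- 2L
  f <- ((rss0 - rss1) / k) / (rss1 / (n - 2L * k))
  max(f)
}

#' supF structural-change test
#'
#' Tests the no-change null (one intercept+trend regression over the
#' whole series) against a single break at an unknown position, using the
#' maximum of the per-split F statistics over all admissible splits. The
#' p-value comes from parametric simulation of the null (iid Gaussian
#' errors; the statistic is scale- and regression-invariant, so simulating
#' pure noise suffices), with the add-one correction
#' `(1 + #{sim >= obs}) / (n_sims + 1)`.
#'
#' @param y Numeric series.
#' @param config A [segmentation_config()] (uses `h`, `n_null_sims`).
#' @return List: `statistic`, `p_value`, `n_sims`.
#' @export
sup_f_test <- function(y, config = segmentation_config()) {
  n <- length(y)
  min_len <- min_segment_length(n, config$h)
  if (n < 2L * min_len)
    stop("series too short for a supF test at h = ", config$h,
         call. = FALSE)
  obs <- sup_f_stat(y, min_len)
  if (!is.finite(obs)) obs <- 0  # flat series: 0/0 F statistics
  if (obs <= .Machine$double.eps^0.5) {
    # flat/degenerate series: no evidence of change
    return(list(statistic = max(obs, 0), p_value = 1,
                n_sims = config$n_null_sims))
  }
  null <- vapply(seq_len(config$n_null_sims), function(i)
    sup_f_stat(stats::rnorm(n), min_len), numeric(1))
  p <- (1 + sum(null >= obs)) / (config$n_null_sims + 1)
  list(statistic = obs, p_value = p, n_sims = config$n_null_sims)
}

#' Segment a daily soil-moisture record into drought periods
#'
#' Aggregates a sensor table to the daily catena mean, fills interior
#' gaps of up to `max_gap_days` by linear interpolation (longer gaps
#' split the record; the longest contiguous run is segmented, with a
#' warning), and runs [select_n_breaks()].
#'
#' @param sensors Sensor data.frame (columns `date`, `moisture`).
#' @param config A [segmentation_config()].
#' @param max_gap_days Longest gap bridged by interpolation (default 3).
#' @return A `segmentation_result` (see [select_n_breaks()]); its
#'   `breakpoint_dates` define the drought periods consumed downstream.
#' @export
segment_moisture <- function(sensors, config = segmentation_config(),
                             max_gap_days = 3L) {
  daily <- daily_catena_moisture(sensors)
  full <- data.frame(date = seq(min(daily$date), max(daily$date),
                                by = "day"))
  full$moisture <- daily$moisture[match(full$date, daily$date)]
  gap <- is.na(full$moisture)
  if (any(gap)) {
    r <- rle(gap)
    long <- r$values & r$lengths > max_gap_days
    if (any(long)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ok_runs <- !r$values
      # longest observed run between long gaps
      block <- cumsum(r$values & r$lengths > max_gap_days)
      spans <- lapply(split(seq_along(r$values), block), function(idx) {
        idx <- idx[!r$values[idx]]
        if (!length(idx)) return(NULL)
        c(starts[min(idx)], ends[max(idx)])
      })
      spans <- Filter(Negate(is.null), spans)
      len <- vapply(spans, function(s) s[2L] - s[1L] + 1L, numeric(1))
      keep <- spans[[which.max(len)]]
      warning("record has gaps longer than ", max_gap_days,
              " days; segmenting the longest contiguous span (",
              format(full$date[keep[1L]]), " to ",
              format(full$date[keep[2L]]), ")", call. = FALSE)
      full <- full[keep[1L]:keep[2L], , drop = FALSE]
    }
    obs <- which(!is.na(full$moisture))
    full$moisture <- stats::approx(obs, full$moisture[obs],
                                   xout = seq_len(nrow(full)),
                                   rule = 2)$y
  }
  select_n_breaks(full$moisture, config, dates = full$date)
}
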