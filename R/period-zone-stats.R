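# Drought-period x topographic-zone summaries, the two-way (repeated
# measures) ANOVA with Tukey HSD follow-up, and hot-moment detection.

#' Summarize a variable by drought period and topographic zone
#'
#' One row per grouping cell present in the data with n, mean, s.d.,
#' s.e.m. (= s.d. / sqrt(n)) and the 90th percentile (type-7 linear
#' interpolation; worth stating because published hot-moment thresholds
#' depend on the quantile convention). Empty cells are omitted.
#'
#' @param data data.frame containing `variable` and the grouping columns.
#' @param variable Name of the value column.
#' @param grouping Character vector of grouping columns (default
#'   `c("period", "zone")`).
#' @return data.frame: grouping columns plus `n`, `mean`, `sd`, `sem`,
#'   `p90`.
#' @export
#' @examples
#' df <- data.frame(period = "drought", zone = "slope", flux = c(1, 2, 3))
#' summarize_period_zone(df, "flux")
summarize_period_zone <- function(data, variable,
                                  grouping = c("period", "zone")) {
  stopifnot(variable %in% names(data), all(grouping %in% names(data)))
  x <- data[[variable]]
  keys <- lapply(grouping, function(g) as.character(data[[g]]))
  names(keys) <- grouping
  split_idx <- split(seq_along(x), keys, drop = TRUE, sep = "\r")
  rows <- lapply(names(split_idx), function(nm) {
    v <- x[split_idx[[nm]]]
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    lv <- strsplit(nm, "\r", fixed = TRUE)[[1L]]
    cell <- as.data.frame(as.list(stats::setNames(lv, grouping)),
                          stringsAsFactors = FALSE)
    cell$variable <- variable
    cell$n <- length(v)
    cell$mean <- mean(v)
    cell$sd <- if (length(v) > 1L) stats::sd(v) else 0
    cell$sem <- cell$sd / sqrt(cell$n)
    cell$p90 <- unname(stats::quantile(v, 0.9, type = 7))
    cell
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out[do.call(order, out[grouping]), , drop = FALSE]
}

extract_aov_terms <- function(fit) {
  # returns data.frame(term, df, f, p) from aov or aovlist
  strata <- if (inherits(fit, "aovlist")) summary(fit) else
    list(summary(fit))
  rows <- list()
  for (s in strata) {
    tab <- if (is.list(s) && !is.data.frame(s[[1L]])) s[[1L]] else s[[1L]]
    tab <- as.data.frame(if (is.list(s)) s[[1L]] else s)
    nm <- trimws(rownames(tab))
    for (i in seq_len(nrow(tab))) {
      if (nm[i] == "Residuals") next
      rows[[length(rows) + 1L]] <- data.frame(
        term = nm[i], df = tab$Df[i],
        f = if ("F value" %in% names(tab)) tab[["F value"]][i] else NA_real_,
        p = if ("Pr(>F)" %in% names(tab)) tab[["Pr(>F)"]][i] else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-way (optionally repeated-measures) ANOVA with Tukey HSD
#'
#' Models a response by drought period, topographic zone and their
#' interaction. In the repeated-measures design the chamber is the
#' subject: zone (a between-subject factor) is tested in the chamber
#' stratum and period and the interaction in the chamber-by-period
#' stratum, via `aov` with an `Error(subject/period)` term. Optionally
#' log-transforms the response first (the convention for soil CO2 fluxes,
#' which are positive and right-skewed; CH4 fluxes are sign-indefinite
#' and must stay untransformed). Tukey-adjusted pairwise contrasts for
#' the main factors come from `emmeans`.
#'
#' @param data data.frame with the response, `period`, `zone` and (for
#'   repeated measures) the subject column.
#' @param response Response column name.
#' @param repeated Use the repeated-measures error structure?
#' @param log_transform Log-transform the response (requires all values
#'   positive)?
#' @param subject Subject identifier column (default `"chamber_id"`).
#' @param tukey Compute Tukey HSD contrasts (default TRUE).
#' @return Object of class `anova_result`: `response`, `design`,
#'   `transform`, `terms` (data.frame `term`, `df`, `f`, `p`),
#'   `tukey` (data.frame `factor`, `contrast`, `estimate`, `p_adj`, or
#'   NULL).
#' @export
anova_period_zone <- function(data, response, repeated = FALSE,
                              log_transform = FALSE,
                              subject = "chamber_id", tukey = TRUE) {
  stopifnot(response %in% names(data),
            all(c("period", "zone") %in% names(data)))
  dat <- data.frame(y = data[[response]],
                   period = factor(as.character(data$period)),
                   zone = factor(as.character(data$zone)))
  if (nlevels(dat$period) < 2L)
    stop("factor `period` has a single level", call. = FALSE)
  if (nlevels(dat$zone) < 2L)
    stop("factor `zone` has a single level", call. = FALSE)
  cells <- table(dat$period, dat$zone)
  if (any(cells == 0L)) {
    i <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop("design cell (period=", rownames(cells)[i[1L]], ", zone=",
         colnames(cells)[i[2L]], ") is empty", call. = FALSE)
  }
  if (log_transform) {
    if (any(dat$y <= 0))
      stop("log transform requires strictly positive responses",
           call. = FALSE)
    dat$y <- log(dat$y)
  }
  # fit with sum-to-zero contrasts up front so emmeans does not try to
  # re-evaluate the model call (the F tests are unaffected)
  ctr <- list(period = "contr.sum", zone = "contr.sum")
  env <- new.env(parent = globalenv())
  if (repeated) {
    if (!subject %in% names(data))
      stop("repeated-measures design needs subject column `", subject,
           "`", call. = FALSE)
    dat$subject <- factor(as.character(data[[subject]]))
    form <- stats::as.formula("y ~ period * zone + Error(subject / period)",
                              env = env)
  } else {
    form <- stats::as.formula("y ~ period * zone", env = env)
  }
  env$dat <- dat
  fit <- eval(bquote(stats::aov(.(form), data = dat, contrasts = .(ctr))),
              env)
  terms <- extract_aov_terms(fit)
  tk <- NULL
  if (tukey) {
    tk <- do.call(rbind, lapply(c("period", "zone"), function(fac) {
      em <- suppressMessages(
        emmeans::emmeans(fit, stats::as.formula(paste0("~", fac)),
                         data = dat))
      pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                            adjust = "tukey"))
      data.frame(factor = fac, contrast = pr$contrast,
                 estimate = pr$estimate, p_adj = pr$p.value)
    }))
    rownames(tk) <- NULL
  }
  structure(list(response = response,
                 design = if (repeated) "two_way_repeated" else "two_way",
                 transform = if (log_transform) "log" else "none",
                 terms = terms, tukey = tk),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA (", x$design, ") on ", x$response,
      if (x$transform != "none") paste0(" [", x$transform, "]"), "\n",
      sep = "")
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Hot-moment detection by the per-period 90th percentile
#'
#' Flags observations above their drought period's 90th-percentile flux
#' — the "hot moment" rule. Requires at least 10 observations per period
#' so the threshold is interior to the data.
#'
#' @param data data.frame with `period` and the flux column.
#' @param variable Flux column name (default `"flux"`).
#' @param quantile Threshold quantile (default 0.9).
#' @return List: `thresholds` (data.frame `period`, `threshold`, `n`,
#'   `n_hot`) and `data` (the input with logical `hot` appended).
#' @export
hot_moments <- function(data, variable = "flux", quantile = 0.9) {
  stopifnot(variable %in% names(data), "period" %in% names(data))
  x <- data[[variable]]
  per <- as.character(data$period)
  counts <- table(per)
  if (any(counts < 10L))
    stop("period(s) with fewer than 10 observations: ",
         paste(names(counts)[counts < 10L], collapse = ", "),
         call. = FALSE)
  thr <- tapply(x, per, stats::quantile, probs = quantile, type = 7)
  data$hot <- x > unname(thr[per])
  tab <- data.frame(period = names(thr), threshold = unname(thr),
                    n = as.integer(counts[names(thr)]),
                    n_hot = as.integer(tapply(data$hot, per, sum)[names(thr)]))
  rownames(tab) <- NULL
  list(thresholds = tab, data = data)
}
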