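# End-to-end pipeline: simulate -> fluxes -> segment -> summarize ->
# upscale, each stage reading/writing the documented on-disk interfaces,
# with a provenance manifest.

#' Pipeline configuration
#'
#' Bundles per-stage settings and toggles for [run_pipeline()]. The demo
#' defaults keep the chamber stage light (closures every `trace_every`
#' days, `closures_per_day` per chamber) while spanning all four drought
#' periods; the sensor and rainfall records are always full length.
#'
#' @param seed Master seed; every stochastic stage derives its stream
#'   from it.
#' @param catena A [catena_config()] (its seed is overridden by `seed`).
#' @param qc A [qc_policy()].
#' @param segmentation A [segmentation_config()].
#' @param upscaling An [upscaling_config()] (seed overridden by `seed`).
#' @param trace_every Day spacing of simulated chamber closures.
#' @param closures_per_day Closures per chamber per sampled day.
#' @param malfunctions A [malfunction_spec()] injected into the traces.
#' @param stages Named logical: which of `simulate`, `fluxes`, `segment`,
#'   `summarize`, `upscale` to run. Later stages read earlier stages'
#'   outputs from `out_dir`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            catena = catena_config(seed = seed),
                            qc = qc_policy(),
                            segmentation = segmentation_config(),
                            upscaling = upscaling_config(seed = seed),
                            trace_every = 10L,
                            closures_per_day = 2L,
                            malfunctions = malfunction_spec(),
                            stages = c(simulate = TRUE, fluxes = TRUE,
                                       segment = TRUE, summarize = TRUE,
                                       upscale = TRUE)) {
  catena$seed <- as.integer(seed)
  upscaling$seed <- as.integer(seed)
  upscaling$breakpoint_dates <- catena$breakpoint_dates
  st <- c(simulate = TRUE, fluxes = TRUE, segment = TRUE,
          summarize = TRUE, upscale = TRUE)
  st[names(stages)] <- stages
  structure(list(seed = as.integer(seed), catena = catena, qc = qc,
                 segmentation = segmentation, upscaling = upscaling,
                 trace_every = as.integer(trace_every),
                 closures_per_day = as.integer(closures_per_day),
                 malfunctions = malfunctions, stages = st),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys override the corresponding
#' [pipeline_config()] arguments (`seed`, `trace_every`,
#' `closures_per_day`, `stages`, plus scalar fields of the nested
#' `catena`, `qc`, `segmentation` and `upscaling` blocks).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = if (!is.null(y$seed)) y$seed else 1L)
  for (f in c("trace_every", "closures_per_day"))
    if (!is.null(y[[f]])) cfg[[f]] <- as.integer(y[[f]])
  if (!is.null(y$stages)) cfg$stages[names(y$stages)] <-
    vapply(y$stages, isTRUE, logical(1))
  for (block in c("catena", "qc", "segmentation", "upscaling")) {
    for (f in names(y[[block]])) {
      if (!f %in% names(cfg[[block]]))
        stop("unknown ", block, " setting `", f, "`", call. = FALSE)
      val <- y[[block]][[f]]
      if (inherits(cfg[[block]][[f]], "Date")) val <- as.Date(val)
      cfg[[block]][[f]] <- val
    }
  }
  cfg$catena$seed <- cfg$seed
  cfg$upscaling$seed <- cfg$seed
  cfg
}

#' Run the full catena drought analysis pipeline
#'
#' Chains the stages simulate (synthetic sensors, rainfall, chamber
#' traces, soil chemistry + ground truth), fluxes (QC-filtered chamber
#' flux table), segment (drought periods from the moisture record),
#' summarize (period x zone summaries, ANOVA, hot moments) and upscale
#' (Monte Carlo cumulative CO2e per scenario and the CH4 offset
#' statistic), writing each stage's outputs into `out_dir` and a
#' `manifest.json` recording files, md5 checksums, seed and package
#' version. Reruns with the same config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  skipped <- names(st)[!st]

  if (st[["simulate"]]) {
    sens <- generate_sensor_series(config$catena)
    write_table(transform(sens$sensors,
                          timestamp = format(timestamp,
                                             "%Y-%m-%dT%H:%M:%SZ",
                                             tz = "UTC")),
                file.path(out_dir, "sensors.csv"))
    rain <- generate_rainfall(config$catena)
    write_table(rain$rainfall, file.path(out_dir, "rainfall.csv"))
    trace_days <- seq(config$upscaling$study_start,
                      min(config$catena$end_date,
                          config$upscaling$study_start +
                            config$upscaling$study_days - 1L),
                      by = paste(config$trace_every, "days"))
    tr <- generate_chamber_traces(
      config$catena, malfunctions = config$malfunctions,
      dates = trace_days, closures_per_day = config$closures_per_day)
    write_traces(tr$traces, file.path(out_dir, "traces"))
    chem <- generate_soil_chem(config$catena)
    write_table(chem$soil_chem, file.path(out_dir, "soil_chem.csv"))
    jsonlite::write_json(
      list(breakpoint_dates = format(sens$truth$breakpoint_dates),
           sensor_truth = sens$truth[c("shared_sd", "shared_ar1",
                                       "transition_days",
                                       "interpolated_periods")],
           flux_truth = tr$truth,
           chem_truth = chem$truth$chem_means,
           seed = config$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }

  if (st[["fluxes"]]) {
    traces <- read_traces(file.path(out_dir, "traces"))
    fluxes <- estimate_fluxes(traces, config$qc)
    fluxes$closure_start <- format(fluxes$closure_start,
                                   "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    write_table(fluxes, file.path(out_dir, "fluxes.csv"))
  }

  if (st[["segment"]]) {
    sensors <- read_table(file.path(out_dir, "sensors.csv"),
                          sensor_schema())
    seg <- segment_moisture(sensors, config$segmentation)
    write_segments(seg, file.path(out_dir, "segments.json"))
  }

  if (st[["summarize"]]) {
    fluxes <- read_table(file.path(out_dir, "fluxes.csv"), flux_schema())
    seg <- read_segments(file.path(out_dir, "segments.json"))
    bps <- as.Date(seg$breakpoint_dates)
    if (length(bps) != 3L)  # fall back to the configured calendar
      bps <- config$catena$breakpoint_dates
    fluxes <- fluxes[fluxes$retained, , drop = FALSE]
    fluxes$period <- assign_period(fluxes$date, bps)
    summaries <- do.call(rbind, lapply(c("CO2", "CH4"), function(g)
      cbind(gas = g,
            summarize_period_zone(fluxes[fluxes$gas == g, ], "flux"))))
    write_table(summaries, file.path(out_dir, "summaries.csv"))
    hm <- hot_moments(fluxes[fluxes$gas == "CH4", ], "flux")
    write_table(hm$thresholds, file.path(out_dir, "hot_moments.csv"))
    anova_out <- lapply(c(CO2 = "CO2", CH4 = "CH4"), function(g) {
      dd <- fluxes[fluxes$gas == g, ]
      # the log transform needs positive values; a retained CO2 flux can
      # still sit at/below zero through analyzer noise on tiny fluxes
      if (g == "CO2") dd <- dd[dd$flux > 0, , drop = FALSE]
      a <- anova_period_zone(dd, "flux", repeated = TRUE,
                             log_transform = (g == "CO2"))
      list(design = a$design, transform = a$transform, terms = a$terms,
           tukey = a$tukey)
    })
    jsonlite::write_json(anova_out, file.path(out_dir, "anova.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (st[["upscale"]]) {
    summaries <- read_table(file.path(out_dir, "summaries.csv"),
                            c(gas = "character", period = "character",
                              zone = "character", mean = "numeric",
                              sd = "numeric"))
    ucfg <- config$upscaling
    res <- list()
    for (g in c("CO2", "CH4")) for (sc in c("observed", "baseline")) {
      mc <- run_monte_carlo(summaries, ucfg, gas = g, scenario = sc)
      res[[paste(g, sc, sep = "_")]] <-
        mc[c("total", "ci_low", "ci_high", "per_period", "n_days")]
    }
    sink_mc <- run_monte_carlo(summaries, ucfg, gas = "CH4",
                               window = c(ucfg$breakpoint_dates[1L],
                                          ucfg$breakpoint_dates[3L] - 1L))
    reb_mc <- run_monte_carlo(summaries, ucfg, gas = "CH4",
                              window = c(ucfg$breakpoint_dates[3L],
                                         ucfg$breakpoint_dates[3L] +
                                           ucfg$post_drought_window_days -
                                           1L))
    off <- tryCatch(offset_fraction(sink_mc$draws, reb_mc$draws),
                    error = function(e) NULL)
    if (!is.null(off))
      res$offset <- off[c("sink", "rebound", "offset_pct", "ci_low_pct",
                          "ci_high_pct", "n_excluded")]
    jsonlite::write_json(res, file.path(out_dir, "emissions.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("catenaflux")),
    stages_run = names(st)[st],
    stages_skipped = skipped,
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
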