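# Schema-validated delimited-table IO and JSON/YAML round-tripping for
# the pipeline's on-disk interfaces. CSV, header row, UTF-8, '.' decimal,
# ISO-8601 dates throughout.

#' Read a delimited table against a column schema
#'
#' Reads a CSV, checks that every schema column is present, coerces each
#' to its declared type, and reports offending rows by line number.
#' Supported types: `"character"`, `"numeric"`, `"integer"`, `"logical"`,
#' `"Date"` (ISO-8601), `"POSIXct"` (UTC).
#'
#' @param path File path.
#' @param schema Named character vector: column name -> type.
#' @param key Optional character vector of columns whose combination must
#'   be unique; duplicates are an error.
#' @return data.frame with coerced columns (schema columns first; extra
#'   columns preserved).
#' @export
read_table <- function(path, schema, key = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols))
    stop("`", basename(path), "` is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in names(schema)) {
    v <- raw[[col]]
    coerced <- switch(schema[[col]],
      character = v,
      numeric = suppressWarnings(as.numeric(v)),
      integer = suppressWarnings(as.integer(v)),
      logical = as.logical(v),
      Date = as.Date(v, format = "%Y-%m-%d"),
      POSIXct = as.POSIXct(v, tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                          "%Y-%m-%dT%H:%M:%OS",
                                          "%Y-%m-%d %H:%M:%OS",
                                          "%Y-%m-%d")),
      stop("unknown schema type `", schema[[col]], "`", call. = FALSE))
    bad <- which(is.na(coerced) & !(is.na(v) | v == "" | v == "NA"))
    if (length(bad))
      stop("`", basename(path), "` column `", col, "`: unparseable ",
           schema[[col]], " value(s) at data row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    raw[[col]] <- coerced
  }
  if (!is.null(key)) {
    kk <- do.call(paste, c(raw[key], sep = "\r"))
    if (anyDuplicated(kk))
      stop("`", basename(path), "` has duplicated key (",
           paste(key, collapse = ", "), ") at data row(s) ",
           paste(utils::head(which(duplicated(kk)), 5L), collapse = ", "),
           call. = FALSE)
  }
  raw
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_table
#' @format NULL
#' @details `sensor_schema()`, `flux_schema()`, `rainfall_schema()` and
#'   `soil_chem_schema()` are the canonical schemas of the pipeline's
#'   table interfaces.
#' @export
sensor_schema <- function() {
  c(timestamp = "POSIXct", date = "Date", transect = "integer",
    position = "integer", zone = "character", moisture = "numeric",
    o2_pct = "numeric", temp_c = "numeric")
}

#' @rdname read_table
#' @export
flux_schema <- function() {
  c(trace_idx = "integer", chamber_id = "character", zone = "character",
    closure_start = "POSIXct", date = "Date", gas = "character",
    flux = "numeric", se = "numeric", model = "character",
    uncertainty_ratio = "numeric", qc_flags = "character",
    retained = "logical")
}

#' @rdname read_table
#' @export
rainfall_schema <- function() {
  c(date = "Date", rain_mm = "numeric", year_type = "character")
}

#' @rdname read_table
#' @export
soil_chem_schema <- function() {
  c(period = "character", zone = "character", replicate = "integer",
    analyte = "character", value = "numeric")
}

#' Write / read chamber traces as per-closure CSV files with a manifest
#'
#' Each closure becomes `trace_<id>.csv` (`t_s, co2_ppm, ch4_ppb`);
#' `manifest.csv` carries the closure metadata (chamber, zone, start,
#' duration, covariates, geometry, ambient concentrations).
#'
#' @param traces List of [chamber_trace()] objects.
#' @param dir Output directory (created if needed).
#' @return `write_traces()` the directory, invisibly; `read_traces()` the
#'   list of traces.
#' @export
write_traces <- function(traces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(trace_file = sprintf("trace_%05d.csv", i),
               chamber_id = tr$chamber_id, zone = tr$zone,
               closure_start = format(tr$closure_start,
                                      "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               duration_s = tr$duration_s, temp_c = tr$temp_c,
               rh_pct = tr$rh_pct, press_kpa = tr$press_kpa,
               volume_m3 = tr$volume_m3, area_m2 = tr$area_m2,
               ambient_co2_ppm = tr$ambient[["CO2"]],
               ambient_ch4_ppb = tr$ambient[["CH4"]])
  }))
  for (i in seq_along(traces))
    write_table(traces[[i]]$samples,
                file.path(dir, sprintf("trace_%05d.csv", i)))
  write_table(man, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' @rdname write_traces
#' @export
read_traces <- function(dir) {
  man <- read_table(file.path(dir, "manifest.csv"),
                    c(trace_file = "character", chamber_id = "character",
                      zone = "character", closure_start = "POSIXct",
                      duration_s = "numeric", temp_c = "numeric",
                      rh_pct = "numeric", press_kpa = "numeric",
                      volume_m3 = "numeric", area_m2 = "numeric",
                      ambient_co2_ppm = "numeric",
                      ambient_ch4_ppb = "numeric"))
  lapply(seq_len(nrow(man)), function(i) {
    samples <- read_table(file.path(dir, man$trace_file[i]),
                          c(t_s = "numeric", co2_ppm = "numeric",
                            ch4_ppb = "numeric"))
    chamber_trace(
      chamber_id = man$chamber_id[i], zone = man$zone[i],
      closure_start = man$closure_start[i], samples = samples,
      temp_c = man$temp_c[i], rh_pct = man$rh_pct[i],
      press_kpa = man$press_kpa[i], volume_m3 = man$volume_m3[i],
      area_m2 = man$area_m2[i],
      ambient = c(CO2 = man$ambient_co2_ppm[i],
                  CH4 = man$ambient_ch4_ppb[i]),
      duration_s = man$duration_s[i])
  })
}

#' Persist a segmentation result as JSON
#'
#' @param seg A `segmentation_result`.
#' @param path Output path (`segments.json`).
#' @return The path, invisibly.
#' @export
write_segments <- function(seg, path) {
  jsonlite::write_json(list(
    chosen_n_breaks = seg$chosen_n_breaks,
    breakpoints = seg$breakpoints,
    breakpoint_dates = if (!is.null(seg$breakpoint_dates))
      format(seg$breakpoint_dates) else NULL,
    bic_table = seg$bic_table,
    segments = seg$segments,
    sup_f = seg$sup_f,
    p_value = seg$p_value,
    n = seg$n), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
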