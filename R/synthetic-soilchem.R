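# Synthetic soil-chemistry sampling campaign: two periods (pre-drought,
# drought peak) x three zones x five analytes, six replicates per cell.

#' Default soil-chemistry cell means
#'
#' Mean analyte values per sampling period and topographic zone. The
#' drought/pre-drought ratios encode the published effect directions:
#' inorganic P falls (by 60% in valleys), organic P rises (valleys +301%,
#' ridges +126%, slopes +56%), Fe(II) falls and Fe(III) rises as soils
#' aerate, and valley pH drops. Absolute concentrations (µg g-1 dry soil)
#' are plausible inventions for clay-rich Ultisols.
#'
#' @return data.frame: `period`, `zone`, `analyte`, `mean`, `sd`.
#' @export
default_soil_chem_means <- function() {
  rows <- expand.grid(period = c("pre_drought", "drought"),
                      zone = c("ridge", "slope", "valley"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vals <- list(
    #            ridge          slope          valley
    inorganic_p = list(pre = c(2.0, 2.5, 6.0),
                       dr  = c(1.4, 1.6, 2.4)),    # valley -60%
    organic_p   = list(pre = c(120, 125, 130),
                       dr  = c(271.2, 195, 521.3)), # +126% / +56% / +301%
    fe2         = list(pre = c(5, 20, 200),
                       dr  = c(3, 10, 80)),
    fe3         = list(pre = c(300, 350, 250),
                       dr  = c(330, 400, 340)),
    ph          = list(pre = c(4.8, 4.9, 5.2),
                       dr  = c(4.8, 4.9, 4.9)))
  zi <- match(rows$zone, c("ridge", "slope", "valley"))
  out <- do.call(rbind, lapply(names(vals), function(a) {
    v <- ifelse(rows$period == "pre_drought",
                vals[[a]]$pre[zi], vals[[a]]$dr[zi])
    data.frame(period = rows$period, zone = rows$zone, analyte = a,
               mean = v,
               sd = if (a == "ph") 0.1 else 0.12 * v)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic soil-chemistry table
#'
#' Draws `n_replicates` Gaussian replicates per period x zone x analyte
#' cell. Concentrations are truncated at zero from below; pH is clamped
#' to \[2, 9\].
#'
#' @param config A [catena_config()]; `config$seed + 4` seeds the draws.
#' @param chem_means Cell-mean table ([default_soil_chem_means()]); must
#'   cover 2 periods x 3 zones x 5 analytes.
#' @param n_replicates Replicates per cell (default 6).
#' @return List with `soil_chem` (data.frame: `period`, `zone`,
#'   `replicate`, `analyte`, `value`) and `truth` (the mean table and
#'   seed).
#' @export
generate_soil_chem <- function(config,
                               chem_means = default_soil_chem_means(),
                               n_replicates = 6L) {
  if (any(!is.finite(chem_means$mean)) || any(!is.finite(chem_means$sd)))
    stop("soil-chemistry means and sds must all be finite", call. = FALSE)
  need <- expand.grid(period = c("pre_drought", "drought"),
                      zone = c("ridge", "slope", "valley"),
                      analyte = c("inorganic_p", "organic_p", "fe2",
                                  "fe3", "ph"),
                      stringsAsFactors = FALSE)
  key <- paste(chem_means$period, chem_means$zone, chem_means$analyte)
  miss <- !(paste(need$period, need$zone, need$analyte) %in% key)
  if (any(miss)) {
    i <- which(miss)[1L]
    stop("soil-chemistry means missing cell (", need$period[i], ", ",
         need$zone[i], ", ", need$analyte[i], ")", call. = FALSE)
  }
  set.seed(config$seed + 4L)
  out <- chem_means[rep(seq_len(nrow(chem_means)), each = n_replicates), ]
  out$replicate <- rep(seq_len(n_replicates), times = nrow(chem_means))
  out$value <- stats::rnorm(nrow(out), out$mean, out$sd)
  is_ph <- out$analyte == "ph"
  out$value[!is_ph] <- pmax(out$value[!is_ph], 0)
  out$value[is_ph] <- pmin(pmax(out$value[is_ph], 2), 9)
  soil_chem <- out[, c("period", "zone", "replicate", "analyte", "value")]
  rownames(soil_chem) <- NULL
  list(soil_chem = soil_chem,
       truth = list(chem_means = chem_means, seed = config$seed))
}
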