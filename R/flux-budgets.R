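#' Global-warming-potential conversion constants
#'
#' The 100-year global warming potentials and mass conversion factors used in
#' all CO2-equivalent arithmetic. The carbon-to-CO2 factor is the conventional
#' 3.664 (not 44/12 recomputed), CH4 and N2O GWPs are the 100-year values 25
#' and 298, and the molecular-mass ratios convert CH4-C to CH4 and N2O-N to
#' N2O.
#'
#' @return named list of constants: `gwp_ch4`, `gwp_n2o`, `c_to_co2`,
#'   `n2o_n_to_n2o`, `ch4_c_to_ch4`.
#' @export
gwp_constants <- function() {
  list(
    gwp_ch4      = 25,
    gwp_n2o      = 298,
    c_to_co2     = 3.664,
    n2o_n_to_n2o = 44 / 28,
    ch4_c_to_ch4 = 16 / 12
  )
}

#' Fill gaps in a half-hourly flux series by diurnal analogy
#'
#' Replaces each gap with the mean of measured values at the same time of day
#' within a moving window of +/- 7 days around the gap; the window is widened
#' in 7-day increments until at least three donor values exist. This is a
#' deliberately simple stand-in for meteorological-covariate gap-filling: it
#' preserves the diurnal cycle, which dominates half-hourly NEE.
#'
#' Original (measured) values are never altered; filled records are flagged
#' `qc = 2`.
#'
#' @param series a [flux_series()]; must contain < 50% gaps.
#' @return a gap-free `flux_series` with filled records flagged.
#' @export
gapfill_diurnal <- function(series) {
  stopifnot(inherits(series, "flux_series"))
  gap <- series$qc == 1L | is.na(series$flux)
  if (!any(gap)) return(series)
  if (mean(gap) >= 0.5) {
    stop("series has >= 50% gaps; refusing to gap-fill", call. = FALSE)
  }
  tod <- format(series$timestamp, "%H:%M")
  day <- as.numeric(series$timestamp) / 86400
  flux <- series$flux
  qc <- series$qc
  for (slot in unique(tod[gap])) {
    in_slot <- tod == slot
    donors <- which(in_slot & !gap)
    if (length(donors) == 0L) {
      stop("no donor values at time of day ", slot, call. = FALSE)
    }
    for (i in which(in_slot & gap)) {
      w <- 7
      repeat {
        sel <- donors[abs(day[donors] - day[i]) <= w]
        if (length(sel) >= 3L || length(sel) == length(donors)) break
        w <- w + 7
      }
      flux[i] <- mean(series$flux[sel])
      qc[i] <- 2L
    }
  }
  out <- series
  out$flux <- flux
  out$qc <- qc
  out
}

# number of whole calendar months spanned, or stop() if the series does not
# cover whole months end to end
.whole_months <- function(timestamp) {
  first <- timestamp[1]
  last <- timestamp[length(timestamp)]
  if (format(first, "%d %H:%M") != "01 00:00") {
    stop("series must start at the first half-hour of a month", call. = FALSE)
  }
  nxt <- last + 1800
  if (format(nxt, "%d %H:%M") != "01 00:00") {
    stop("series must end at the last half-hour of a month", call. = FALSE)
  }
  length(unique(format(timestamp, "%Y-%m")))
}

#' Annual NEE from a gap-free half-hourly series
#'
#' Sums a gap-free half-hourly series covering `m` whole calendar months to a
#' period carbon total and linearly extrapolates to 12 months
#' (total x 12 / m). Fluxes in µmol CO2 m-2 s-1 are converted to carbon mass
#' per half-hour (x 1800 s x 12.011 µg µmol-1).
#'
#' @param series a gap-free (possibly gap-filled) [flux_series()] covering one
#'   or more whole calendar months.
#' @return annual NEE in gC m-2 yr-1 (positive = source).
#' @export
integrate_annual_nee <- function(series) {
  stopifnot(inherits(series, "flux_series"))
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  if (anyNA(series$flux)) {
    stop("series contains gaps; gap-fill before integrating", call. = FALSE)
  }
  m <- .whole_months(series$timestamp)
  total <- sum(.flux_gc_hh(series))
  total * 12 / m
}

#' Annualize chamber campaigns by trapezoidal integration
#'
#' Computes the campaign mean across replicates per sampling date, then
#' integrates the resulting flux time course trapezoidally over a 365-day
#' (8760 h) year. The first and last campaign values are carried out
#' unchanged to the year boundaries (constant edge extension). Per-gas input
#' units (mgC m-2 h-1 for CO2, µgC m-2 h-1 for CH4, µgN m-2 h-1 for N2O) are
#' converted to annual gC or gN m-2 yr-1.
#'
#' @param campaigns a [chamber_campaign_set()].
#' @param gas one of `"CO2"`, `"CH4"`, `"N2O"`.
#' @param soil_type `"mineral"` or `"peat"`.
#' @param year_start `Date` marking the start of the 365-day integration
#'   window; defaults to the first campaign date.
#' @return annual flux in gC m-2 yr-1 (CO2, CH4) or gN m-2 yr-1 (N2O).
#' @export
trapezoid_annual <- function(campaigns, gas = c("CO2", "CH4", "N2O"),
                             soil_type = c("mineral", "peat"),
                             year_start = NULL) {
  stopifnot(inherits(campaigns, "chamber_campaign_set"))
  gas <- match.arg(gas)
  soil_type <- match.arg(soil_type)
  e <- campaigns$entries
  e <- e[e$gas == gas & e$soil_type == soil_type, , drop = FALSE]
  if (nrow(e) == 0L) stop("no entries for ", gas, "/", soil_type, call. = FALSE)
  mean_by_date <- tapply(e$flux, e$date, mean)
  dates <- as.Date(names(mean_by_date))
  o <- order(dates)
  dates <- dates[o]
  vals <- as.numeric(mean_by_date)[o]
  if (length(dates) < 2L) {
    stop("at least two campaigns are required for annualization", call. = FALSE)
  }
  if (is.null(year_start)) year_start <- dates[1]
  year_end <- year_start + 365
  h <- as.numeric(dates - year_start) * 24
  # constant edge extension to the year boundaries
  if (h[1] > 0) { h <- c(0, h); vals <- c(vals[1], vals) }
  hend <- 365 * 24
  if (h[length(h)] < hend) { h <- c(h, hend); vals <- c(vals, vals[length(vals)]) }
  if (any(h < 0) || any(h > hend)) {
    stop("campaign dates fall outside the one-year window", call. = FALSE)
  }
  integral <- pracma::trapz(h, vals) # per-hour unit x h
  scale <- if (gas == "CO2") 1e-3 else 1e-6 # mg -> g, ug -> g
  integral * scale
}

#' Net ecosystem productivity
#'
#' NEP = NEE + Cyield: net ecosystem exchange plus the carbon exported from
#' the field in harvested fruit. Positive NEP means carbon is removed from
#' the system (the plantation is a net C source once harvest is counted).
#'
#' @param nee annual NEE, gC m-2 yr-1 (positive = source).
#' @param cyield harvest carbon export, gC m-2 yr-1, non-negative.
#' @return NEP in gC m-2 yr-1.
#' @export
nep <- function(nee, cyield) {
  if (any(cyield < 0)) stop("`cyield` must be non-negative", call. = FALSE)
  nee + cyield
}

#' Estimate NEE over peat by soil-respiration substitution
#'
#' Transfers an ecosystem NEE measured over mineral soil to peat by removing
#' the mineral-soil respiration and adding the peat respiration:
#' NEE_peat = NEE_mineral - SR_mineral + SR_peat.
#'
#' @param nee_mineral annual NEE over mineral soil, gC m-2 yr-1.
#' @param sr_mineral,sr_peat annual soil respiration, gC m-2 yr-1, >= 0.
#' @return estimated NEE over peat, gC m-2 yr-1.
#' @export
nee_peat <- function(nee_mineral, sr_mineral, sr_peat) {
  if (any(sr_mineral < 0) || any(sr_peat < 0)) {
    stop("soil respiration must be non-negative", call. = FALSE)
  }
  nee_mineral - sr_mineral + sr_peat
}

#' Estimate NEE for a second-rotation plantation
#'
#' Same substitution as [nee_peat()] but with the (lower) soil respiration
#' expected once soil carbon has approached its post-conversion equilibrium:
#' NEE_2nd = NEE_mineral - SR_mineral + SR_2nd.
#'
#' @inheritParams nee_peat
#' @param sr_second annual soil respiration in the second rotation,
#'   gC m-2 yr-1, >= 0.
#' @return estimated second-rotation NEE, gC m-2 yr-1.
#' @export
nee_second_rotation <- function(nee_mineral, sr_mineral, sr_second) {
  nee_peat(nee_mineral, sr_mineral, sr_second)
}

#' Net global warming potential of the ecosystem budget
#'
#' Converts an annual budget to CO2-equivalents over a 100-year horizon:
#' GWP_net = NEP x 3.664 + CH4-C x (16/12) x 25 + N2O-N x (44/28) x 298.
#'
#' @param nep annual NEP, gC m-2 yr-1.
#' @param ch4 annual soil CH4 flux as CH4-C, gC m-2 yr-1 (negative = uptake).
#' @param n2o annual soil N2O flux as N2O-N, gN m-2 yr-1.
#' @param k constants from [gwp_constants()].
#' @return GWP_net in gCO2-eq m-2 yr-1 (positive = net emission).
#' @export
gwp_net <- function(nep, ch4, n2o, k = gwp_constants()) {
  nep * k$c_to_co2 +
    ch4 * k$ch4_c_to_ch4 * k$gwp_ch4 +
    n2o * k$n2o_n_to_n2o * k$gwp_n2o
}

#' Greenhouse-gas intensity of production
#'
#' GWP_net divided by fresh-fruit-bunch yield: gCO2-eq per g of harvested
#' product. Yield in Mg ha-1 yr-1 is converted to g m-2 yr-1 (x 100).
#'
#' @param gwp_net net GWP, gCO2-eq m-2 yr-1.
#' @param yield FFB yield, Mg ha-1 yr-1, strictly positive.
#' @return GHGI in gCO2-eq g-1 yield.
#' @export
ghgi <- function(gwp_net, yield) {
  if (any(yield <= 0)) {
    stop("GHGI is undefined for zero or negative yield", call. = FALSE)
  }
  gwp_net / (yield * 100)
}

#' Assemble an annual ecosystem greenhouse-gas budget
#'
#' Combines annual NEE, harvest carbon export and soil CH4/N2O fluxes into a
#' one-row budget: NEP, GWP_net and (where yield is non-zero) GHGI.
#'
#' @param nee annual NEE, gC m-2 yr-1.
#' @param cyield harvest C export, gC m-2 yr-1 (0 for non-yielding stands).
#' @param ch4 annual soil CH4-C flux, gC m-2 yr-1.
#' @param n2o annual soil N2O-N flux, gN m-2 yr-1.
#' @param yield FFB yield, Mg ha-1 yr-1, or `NA` if none.
#' @param k constants from [gwp_constants()].
#' @return a one-row data.frame of class `annual_budget` with columns `nee`,
#'   `cyield`, `nep`, `ch4`, `n2o`, `gwp_net`, `ghgi`.
#' @export
annual_budget <- function(nee, cyield = 0, ch4 = 0, n2o = 0, yield = NA,
                          k = gwp_constants()) {
  p <- nep(nee, cyield)
  g <- gwp_net(p, ch4, n2o, k)
  gi <- if (is.na(yield) || yield == 0) NA_real_ else ghgi(g, yield)
  out <- data.frame(
    nee = nee, cyield = cyield, nep = p, ch4 = ch4, n2o = n2o,
    gwp_net = g, ghgi = gi
  )
  class(out) <- c("annual_budget", "data.frame")
  out
}
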