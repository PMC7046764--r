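#' Half-hourly ecosystem flux series
#'
#' Container for a half-hourly net ecosystem exchange (NEE) record as produced
#' by an eddy-covariance system after standard post-processing. Each record is
#' a half-hour slot labelled by its start time; the sign convention throughout
#' the package is positive = flux from the ecosystem into the atmosphere
#' (source), negative = uptake (sink).
#'
#' @param timestamp `POSIXct` vector (UTC recommended), strictly increasing on
#'   a uniform 30-minute step, labelling the start of each half-hour slot.
#' @param flux numeric flux values; `NA` where `qc` marks a gap.
#' @param qc integer quality flag per record: 0 = measured, 1 = gap,
#'   2 = gap-filled.
#' @param unit unit of `flux`: `"umol_m2_s"` (µmol CO2 m-2 s-1, the native
#'   eddy-covariance unit) or `"gC_hh"` (gC m-2 per half-hour).
#'
#' @return A `flux_series`: a data.frame with columns `timestamp`, `flux`,
#'   `qc` and a `unit` attribute.
#' @seealso [gapfill_diurnal()], [integrate_annual_nee()],
#'   [gen_halfhourly_nee()]
#' @export
flux_series <- function(timestamp, flux, qc = 0L,
                        unit = c("umol_m2_s", "gC_hh")) {
  unit <- match.arg(unit)
  if (!inherits(timestamp, "POSIXct")) {
    stop("`timestamp` must be POSIXct", call. = FALSE)
  }
  n <- length(timestamp)
  if (length(flux) != n) stop("`flux` length must match `timestamp`", call. = FALSE)
  qc <- as.integer(rep_len(qc, n))
  if (n > 1) {
    steps <- diff(as.numeric(timestamp))
    if (any(steps <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
    if (any(abs(steps - 1800) > 1e-6)) {
      stop("timestamps must be on a uniform half-hour step", call. = FALSE)
    }
  }
  if (any(qc == 1L & !is.na(flux))) flux[qc == 1L] <- NA_real_
  out <- data.frame(timestamp = timestamp, flux = flux, qc = qc)
  attr(out, "unit") <- unit
  class(out) <- c("flux_series", "data.frame")
  out
}

#' @export
print.flux_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "<flux_series> %d half-hourly records, %s .. %s [%s]\n",
    n, format(x$timestamp[1]), format(x$timestamp[n]), flux_unit(x)
  ))
  cat(sprintf(
    "  gaps: %d (%.1f%%), filled: %d\n",
    sum(x$qc == 1L), 100 * mean(x$qc == 1L), sum(x$qc == 2L)
  ))
  invisible(x)
}

#' @rdname flux_series
#' @param x a `flux_series`
#' @export
flux_unit <- function(x) attr(x, "unit")

# gC per half-hour carried by 1 umol CO2 m-2 s-1 sustained for 1800 s
.GC_PER_UMOL_HH <- 1800 * 12.011 * 1e-6

# flux values converted to gC m-2 per half-hour regardless of declared unit
.flux_gc_hh <- function(series) {
  if (flux_unit(series) == "umol_m2_s") {
    series$flux * .GC_PER_UMOL_HH
  } else {
    series$flux
  }
}
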