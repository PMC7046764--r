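#' Calibrate the post-conversion soil-carbon decay curve
#'
#' After forest is converted to plantation, relative soil carbon stock
#' declines from 100% of the forest reference towards a lower equilibrium.
#' The curve is modelled as exponential decay to an asymptote,
#' `r(t) = f + (1 - f) * exp(-k * t)`, with the asymptote `f` set by
#' `equilibrium_fraction` and the rate `k` solved so that only 1% of the
#' initial excess remains at `equilibrium_time`
#' (`exp(-k * equilibrium_time) = 0.01`).
#'
#' @param reference_stock forest (reference, 100%) soil carbon stock,
#'   kgC m-2.
#' @param equilibrium_fraction asymptotic relative stock, in (0, 1).
#' @param equilibrium_time years after conversion at which the remaining
#'   excess is 1%, > 0. Default 32.5 yr, the midpoint of the 30-35 yr range
#'   over which plantation soil carbon is observed to level off.
#' @return a `decay_curve` with elements `reference_stock`,
#'   `equilibrium_fraction`, `rate` (yr-1), `equilibrium_time` and
#'   `equilibrium_stock` (kgC m-2).
#' @seealso [stock_at()], [respiration_from_anchor()]
#' @export
calibrate_decay <- function(reference_stock, equilibrium_fraction,
                            equilibrium_time = 32.5) {
  if (equilibrium_fraction <= 0 || equilibrium_fraction >= 1) {
    stop("`equilibrium_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (equilibrium_time <= 0) stop("`equilibrium_time` must be > 0", call. = FALSE)
  if (reference_stock <= 0) stop("`reference_stock` must be > 0", call. = FALSE)
  k <- -log(0.01) / equilibrium_time
  structure(
    list(
      reference_stock = reference_stock,
      equilibrium_fraction = equilibrium_fraction,
      rate = k,
      equilibrium_time = equilibrium_time,
      equilibrium_stock = reference_stock * equilibrium_fraction
    ),
    class = "decay_curve"
  )
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf(
    paste0("<decay_curve> reference %.3g kgC m-2, equilibrium fraction %.3g",
           " (stock %.3g kgC m-2)\n  rate %.4g yr-1, equilibrium at %.3g yr\n"),
    x$reference_stock, x$equilibrium_fraction, x$equilibrium_stock,
    x$rate, x$equilibrium_time
  ))
  invisible(x)
}

#' Relative soil carbon stock at time t
#'
#' Evaluates `r(t) = f + (1 - f) * exp(-k * t)` of a calibrated curve.
#'
#' @param curve a [calibrate_decay()] result.
#' @param t years since conversion, >= 0 (vectorized).
#' @return relative stock, dimensionless in (f, 1].
#' @export
relative_stock_at <- function(curve, t) {
  stopifnot(inherits(curve, "decay_curve"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  f <- curve$equilibrium_fraction
  f + (1 - f) * exp(-curve$rate * t)
}

#' Absolute soil carbon stock at time t
#'
#' @inheritParams relative_stock_at
#' @return stock in kgC m-2: `reference_stock * r(t)`.
#' @export
stock_at <- function(curve, t) {
  curve$reference_stock * relative_stock_at(curve, t)
}

#' Scale soil respiration along the decay curve
#'
#' Assumes the relative magnitude of soil respiration after forest conversion
#' follows the same curve over time as relative soil carbon stock. A measured
#' respiration `anchor_flux` at plantation age `anchor_age` is rescaled to any
#' other time: `anchor_flux * r(t) / r(anchor_age)`.
#'
#' @param curve a [calibrate_decay()] result.
#' @param anchor_flux measured soil respiration, mgC m-2 h-1, > 0.
#' @param anchor_age age (yr since conversion) at which it was measured.
#' @param t years since conversion to evaluate at (vectorized); values at or
#'   beyond `equilibrium_time` are effectively the equilibrium respiration.
#' @return soil respiration at `t`, mgC m-2 h-1.
#' @export
respiration_from_anchor <- function(curve, anchor_flux, anchor_age, t) {
  if (anchor_flux <= 0) stop("`anchor_flux` must be > 0", call. = FALSE)
  anchor_flux * relative_stock_at(curve, t) /
    relative_stock_at(curve, anchor_age)
}

#' Convert hourly soil respiration to an annual total
#'
#' @param sr_hourly soil respiration in mgC m-2 h-1.
#' @return gC m-2 yr-1, using an 8760-hour year (x 8.760).
#' @export
sr_hourly_to_annual <- function(sr_hourly) sr_hourly * 8760 / 1000

#' Second-rotation soil-respiration trajectory
#'
#' Annual soil respiration for each year of a second (or later) rotation
#' cycle, evaluated on the decay curve at time-since-original-conversion
#' `start_year + age`. Since the curve is essentially flat past its
#' equilibrium time, a second rotation starting at or after the first cycle's
#' end sits at the equilibrium respiration throughout.
#'
#' @param curve a [calibrate_decay()] result.
#' @param anchor_flux,anchor_age as in [respiration_from_anchor()].
#' @param start_year years since original conversion at which the second
#'   rotation starts (at least the first rotation's cycle length).
#' @param cycle_length length of the second rotation, years (0 gives an empty
#'   trajectory).
#' @return an [annual_trajectory()] of annual soil respiration,
#'   gC m-2 yr-1, for plantation ages 1..`cycle_length`.
#' @export
second_rotation_sr_trajectory <- function(curve, anchor_flux, anchor_age,
                                          start_year, cycle_length) {
  if (cycle_length == 0) {
    return(annual_trajectory(numeric(0), unit = "gC m-2 yr-1"))
  }
  ages <- seq_len(cycle_length)
  hourly <- respiration_from_anchor(curve, anchor_flux, anchor_age,
                                    start_year + ages)
  annual_trajectory(sr_hourly_to_annual(hourly), unit = "gC m-2 yr-1")
}

#' Tabulate a calibrated decay curve
#'
#' Convenience table of age, relative stock, absolute stock and (optionally
#' anchored) soil respiration over the first decades after conversion.
#'
#' @param curve a [calibrate_decay()] result.
#' @param ages years to tabulate (default 0:40).
#' @param anchor_flux,anchor_age optional soil-respiration anchor; if given,
#'   hourly and annual respiration columns are included.
#' @return a data.frame.
#' @export
decay_table <- function(curve, ages = 0:40, anchor_flux = NULL,
                        anchor_age = 1) {
  out <- data.frame(
    age = ages,
    relative_stock = relative_stock_at(curve, ages),
    stock_kgC_m2 = stock_at(curve, ages)
  )
  if (!is.null(anchor_flux)) {
    out$sr_mgC_m2_h <- respiration_from_anchor(curve, anchor_flux, anchor_age,
                                               ages)
    out$sr_gC_m2_yr <- sr_hourly_to_annual(out$sr_mgC_m2_h)
  }
  out
}
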