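#' Year-indexed trajectory over a rotation cycle
#'
#' A numeric vector of annual values indexed by plantation age 1..cycle
#' length, carrying a unit tag. Values are constant within a year.
#'
#' @param values numeric vector, one value per plantation age.
#' @param unit unit tag, e.g. `"gC m-2 yr-1"`, `"Mg ha-1 yr-1"`,
#'   `"kg ha-1 yr-1"`, `"ml ha-1 yr-1"`.
#' @return an `annual_trajectory` (a classed numeric vector).
#' @export
annual_trajectory <- function(values, unit = NA_character_) {
  structure(as.numeric(values), unit = unit, class = "annual_trajectory")
}

#' @export
print.annual_trajectory <- function(x, ...) {
  cat(sprintf("<annual_trajectory> %d years [%s]\n", length(x),
              attr(x, "unit")))
  print(stats::setNames(as.numeric(x), seq_along(x)))
  invisible(x)
}

#' @rdname annual_trajectory
#' @param x an `annual_trajectory`
#' @export
trajectory_unit <- function(x) attr(x, "unit")

#' Plateau-ramp-plateau trajectory
#'
#' The canonical input trajectory over a plantation life cycle: constant at
#' the young-stand level through year `plateau_end`, linear increase to the
#' mature level at year `mature_year`, constant thereafter. The same rule is
#' applied to NEE, fertilizer and herbicide inputs.
#'
#' @param young_value level during years 1..`plateau_end`.
#' @param mature_value level from `mature_year` onwards.
#' @param plateau_end last year of the young plateau (default 3).
#' @param mature_year year at which the mature level is reached (default 8).
#' @param cycle_length rotation length in years.
#' @param unit unit tag for the trajectory.
#' @return an [annual_trajectory()] of length `cycle_length`.
#' @export
ramp_trajectory <- function(young_value, mature_value, plateau_end = 3,
                            mature_year = 8, cycle_length,
                            unit = NA_character_) {
  if (!(plateau_end < mature_year && mature_year <= cycle_length)) {
    stop("need plateau_end < mature_year <= cycle_length", call. = FALSE)
  }
  y <- seq_len(cycle_length)
  v <- ifelse(
    y <= plateau_end, young_value,
    ifelse(y >= mature_year, mature_value,
           young_value + (mature_value - young_value) *
             (y - plateau_end) / (mature_year - plateau_end))
  )
  annual_trajectory(v, unit = unit)
}

#' Define a rotation-cycle management scenario
#'
#' The four scenarios of the life-cycle analysis: business-as-usual (BAU,
#' 25-yr rotation, fruit production from year 4, maximum yield at year 8),
#' scenario A (30-yr rotation), scenario B (40-yr rotation) and scenario C
#' (30-yr rotation with an earlier-yielding variety: first fruit at year 3,
#' near-maximum yield at year 6). All numeric fields can be overridden.
#'
#' @param name one of `"BAU"`, `"A"`, `"B"`, `"C"`.
#' @param rotation `"first"` or `"second"` rotation cycle. Second-rotation
#'   scenarios keep all management parameters but replace the NEE trajectory
#'   (soil respiration at its post-conversion equilibrium) and carry no
#'   land-use-change charge.
#' @param cycle_length rotation length, years; one of 25, 30, 40.
#' @param yield_start_year first fruiting year.
#' @param yield_max_year year of maximum yield.
#' @param nee_young,nee_mature NEE of the young and mature stand,
#'   gC m-2 yr-1.
#' @param max_yield maximum FFB yield, Mg ha-1 yr-1.
#' @param soil_ch4 annual soil CH4-C flux, gC m-2 yr-1 (negative = uptake).
#' @param inputs_young,inputs_mature named lists of input application levels
#'   (n, k, p in kg ha-1 yr-1; glyphosate in ml ha-1 yr-1) for the young and
#'   mature stand.
#' @param input_plateau_end,input_mature_year ramp anchors for NEE and
#'   inputs.
#' @return a validated `scenario_spec` list.
#' @export
scenario_spec <- function(name = c("BAU", "A", "B", "C"),
                          rotation = c("first", "second"),
                          cycle_length = NULL,
                          yield_start_year = NULL,
                          yield_max_year = NULL,
                          nee_young = 1012, nee_mature = -754,
                          max_yield = 26.5,
                          soil_ch4 = -0.13,
                          inputs_young = list(n = 88, k = 73, p = 38,
                                              glyphosate = 0),
                          inputs_mature = list(n = 196, k = 220, p = 50,
                                               glyphosate = 2250),
                          input_plateau_end = 3, input_mature_year = 8) {
  name <- match.arg(name)
  rotation <- match.arg(rotation)
  defaults <- list(
    BAU = list(cycle_length = 25, yield_start_year = 4, yield_max_year = 8),
    A   = list(cycle_length = 30, yield_start_year = 4, yield_max_year = 8),
    B   = list(cycle_length = 40, yield_start_year = 4, yield_max_year = 8),
    C   = list(cycle_length = 30, yield_start_year = 3, yield_max_year = 6)
  )[[name]]
  if (is.null(cycle_length)) cycle_length <- defaults$cycle_length
  if (is.null(yield_start_year)) yield_start_year <- defaults$yield_start_year
  if (is.null(yield_max_year)) yield_max_year <- defaults$yield_max_year
  if (!cycle_length %in% c(25, 30, 40)) {
    stop("`cycle_length` must be one of 25, 30, 40", call. = FALSE)
  }
  if (!(yield_start_year < yield_max_year && yield_max_year <= cycle_length)) {
    stop("need yield_start_year < yield_max_year <= cycle_length",
         call. = FALSE)
  }
  structure(
    list(
      name = name, rotation = rotation, cycle_length = cycle_length,
      yield_start_year = yield_start_year, yield_max_year = yield_max_year,
      nee_young = nee_young, nee_mature = nee_mature, max_yield = max_yield,
      soil_ch4 = soil_ch4,
      inputs_young = inputs_young, inputs_mature = inputs_mature,
      input_plateau_end = input_plateau_end,
      input_mature_year = input_mature_year
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %s, %s rotation, %d-yr cycle; yield years %d..%d, max %.3g Mg ha-1 yr-1\n",
    x$name, x$rotation, x$cycle_length, x$yield_start_year,
    x$yield_max_year, x$max_yield
  ))
  invisible(x)
}

#' Fresh-fruit-bunch yield trajectory
#'
#' Zero before the first fruiting year, then linear from zero (anchored in
#' the year before first production) to `max_yield` at `yield_max_year`,
#' constant afterwards. Supplying `yield_by_age` bypasses the ramp with an
#' explicit yield-by-age table.
#'
#' @param spec a [scenario_spec()].
#' @param yield_by_age optional numeric vector of length `cycle_length`
#'   giving yields (Mg ha-1 yr-1) per age directly.
#' @return an [annual_trajectory()] in Mg ha-1 yr-1.
#' @export
yield_trajectory <- function(spec, yield_by_age = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(yield_by_age)) {
    if (length(yield_by_age) != spec$cycle_length) {
      stop("`yield_by_age` must have one value per year of the cycle",
           call. = FALSE)
    }
    return(annual_trajectory(yield_by_age, unit = "Mg ha-1 yr-1"))
  }
  y <- seq_len(spec$cycle_length)
  anchor0 <- spec$yield_start_year - 1
  v <- ifelse(
    y < spec$yield_start_year, 0,
    ifelse(y >= spec$yield_max_year, spec$max_yield,
           spec$max_yield * (y - anchor0) / (spec$yield_max_year - anchor0))
  )
  annual_trajectory(v, unit = "Mg ha-1 yr-1")
}

#' NEE trajectory over the rotation cycle
#'
#' First rotation: the plateau-ramp-plateau rule from the measured young
#' (source) to mature (sink) NEE. Second rotation: each year of the
#' first-rotation trajectory corrected by soil-respiration substitution
#' (`NEE_2nd = NEE_1st - SR_1st + SR_2nd`), with both respiration terms taken
#' from the calibrated soil-carbon decay curve — `SR_1st` at the plantation's
#' own age, `SR_2nd` at time-since-original-conversion `first_cycle_length +
#' age`.
#'
#' @param spec a [scenario_spec()].
#' @param decay a [calibrate_decay()] curve; required for second rotation.
#' @param sr_anchor_flux measured soil respiration anchoring the curve,
#'   mgC m-2 h-1 (default 133.9, the young-plantation mean).
#' @param sr_anchor_age age of the anchor measurement, years (default 1).
#' @param first_cycle_length length of the preceding first rotation, years.
#' @return an [annual_trajectory()] in gC m-2 yr-1.
#' @export
nee_trajectory <- function(spec, decay = NULL, sr_anchor_flux = 133.9,
                           sr_anchor_age = 1, first_cycle_length = 25) {
  stopifnot(inherits(spec, "scenario_spec"))
  first <- ramp_trajectory(
    spec$nee_young, spec$nee_mature,
    plateau_end = spec$input_plateau_end,
    mature_year = spec$input_mature_year,
    cycle_length = spec$cycle_length, unit = "gC m-2 yr-1"
  )
  if (spec$rotation == "first") return(first)
  if (is.null(decay)) {
    stop("second-rotation NEE requires a calibrated decay curve", call. = FALSE)
  }
  ages <- seq_len(spec$cycle_length)
  sr_first <- sr_hourly_to_annual(
    respiration_from_anchor(decay, sr_anchor_flux, sr_anchor_age, ages)
  )
  sr_second <- second_rotation_sr_trajectory(
    decay, sr_anchor_flux, sr_anchor_age,
    start_year = first_cycle_length, cycle_length = spec$cycle_length
  )
  annual_trajectory(
    nee_second_rotation(as.numeric(first), sr_first, as.numeric(sr_second)),
    unit = "gC m-2 yr-1"
  )
}

#' Input trajectories for a scenario
#'
#' Plateau-ramp-plateau trajectories for every management input (N, K, P
#' fertilizer and glyphosate) of a scenario.
#'
#' @param spec a [scenario_spec()].
#' @return named list of [annual_trajectory()] objects (`n`, `k`, `p` in
#'   kg ha-1 yr-1; `glyphosate` in ml ha-1 yr-1).
#' @export
input_trajectories <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  units <- c(n = "kg ha-1 yr-1", k = "kg ha-1 yr-1", p = "kg ha-1 yr-1",
             glyphosate = "ml ha-1 yr-1")
  out <- lapply(names(units), function(s) {
    ramp_trajectory(spec$inputs_young[[s]], spec$inputs_mature[[s]],
                    plateau_end = spec$input_plateau_end,
                    mature_year = spec$input_mature_year,
                    cycle_length = spec$cycle_length, unit = units[[s]])
  })
  stats::setNames(out, names(units))
}

#' Running mean and cumulative trajectory
#'
#' For a year-indexed trajectory, the running mean at age y is the mean of
#' all values up to and including y; the cumulative value is their sum.
#'
#' @param traj an [annual_trajectory()] (non-empty).
#' @return list with elements `running_mean` and `cumulative`, both
#'   [annual_trajectory()] objects.
#' @export
running_mean_and_cumulative <- function(traj) {
  if (length(traj) == 0L) stop("empty trajectory", call. = FALSE)
  v <- as.numeric(traj)
  cs <- cumsum(v)
  list(
    running_mean = annual_trajectory(cs / seq_along(v),
                                     unit = trajectory_unit(traj)),
    cumulative = annual_trajectory(cs, unit = trajectory_unit(traj))
  )
}
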