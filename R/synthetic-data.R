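#' Parameters for the half-hourly NEE simulator
#'
#' Describes a synthetic half-hourly net-ecosystem-exchange series with a
#' diurnal cycle: constant ecosystem respiration in every slot plus a
#' half-sinusoid photosynthetic drawdown between 06:00 and 18:00. The
#' respiration baseline is solved so that the noise-free, gap-free series
#' integrates exactly to `annual_total` x `months_covered` / 12.
#'
#' @param annual_total target annual NEE, gC m-2 yr-1 (signed, positive =
#'   source).
#' @param diurnal_amplitude peak daytime drawdown, µmol CO2 m-2 s-1, >= 0.
#' @param months_covered integer number of whole months generated (1-12),
#'   starting in January.
#' @param gap_fraction fraction of slots flagged as gaps, in `[0, 0.5)`.
#' @param noise_sd multiplicative noise: per-slot Gaussian noise with standard
#'   deviation `noise_sd` x |flux|.
#' @param seed integer RNG seed.
#' @param year calendar year the series is placed in (non-leap by default so
#'   the 365-day annualization convention holds exactly).
#' @return a validated `nee_sim_params` list.
#' @export
nee_sim_params <- function(annual_total, diurnal_amplitude = 10,
                           months_covered = 12, gap_fraction = 0,
                           noise_sd = 0, seed = 1L, year = 2014L) {
  if (!is.numeric(months_covered) || months_covered < 1 || months_covered > 12 ||
      months_covered != round(months_covered)) {
    stop("`months_covered` must be an integer in 1..12", call. = FALSE)
  }
  if (diurnal_amplitude < 0) stop("`diurnal_amplitude` must be >= 0", call. = FALSE)
  if (gap_fraction < 0 || gap_fraction >= 0.5) {
    stop("`gap_fraction` must be in [0, 0.5)", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(
      annual_total = annual_total, diurnal_amplitude = diurnal_amplitude,
      months_covered = as.integer(months_covered),
      gap_fraction = gap_fraction, noise_sd = noise_sd,
      seed = as.integer(seed), year = as.integer(year)
    ),
    class = "nee_sim_params"
  )
}

#' Generate a synthetic half-hourly NEE series
#'
#' Emulates a post-processed eddy-covariance NEE record: half-hourly fluxes in
#' µmol CO2 m-2 s-1 over `months_covered` whole months with a diurnal cycle,
#' optional multiplicative noise, and gaps placed uniformly at random in whole
#' half-hour slots. Deterministic under a fixed seed.
#'
#' @param params a [nee_sim_params()].
#' @return a [flux_series()] in µmol CO2 m-2 s-1.
#' @export
gen_halfhourly_nee <- function(params) {
  stopifnot(inherits(params, "nee_sim_params"))
  set.seed(params$seed)
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", params$year), tz = "UTC")
  m <- params$months_covered
  t_end <- if (m == 12L) {
    as.POSIXct(sprintf("%d-01-01 00:00:00", params$year + 1L), tz = "UTC")
  } else {
    as.POSIXct(sprintf("%d-%02d-01 00:00:00", params$year, m + 1L), tz = "UTC")
  }
  ts <- seq(t0, t_end - 1800, by = 1800)
  n <- length(ts)
  hour <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  day <- hour >= 6 & hour < 18
  drawdown <- ifelse(day, -params$diurnal_amplitude * sin(pi * (hour - 6) / 12), 0)
  target_gc <- params$annual_total * m / 12
  # respiration baseline solving sum((base + drawdown) * k) == target
  base <- (target_gc / .GC_PER_UMOL_HH - sum(drawdown)) / n
  flux <- base + drawdown
  if (params$noise_sd > 0) {
    flux <- flux + stats::rnorm(n, 0, params$noise_sd * abs(flux))
  }
  qc <- integer(n)
  if (params$gap_fraction > 0) {
    gaps <- sample.int(n, floor(params$gap_fraction * n))
    qc[gaps] <- 1L
    flux[gaps] <- NA_real_
  }
  flux_series(ts, flux, qc, unit = "umol_m2_s")
}

#' Parameters for the chamber-campaign simulator
#'
#' Describes repeated static-chamber campaigns measuring soil CO2 (soil
#' respiration, SR), CH4 and N2O fluxes on mineral and peat soil, with a
#' configurable peat/mineral SR contrast and fertilization-driven N2O pulses.
#' SR draws are lognormal (strictly positive); CH4 and N2O draws are normal
#' (both signs occur in the field). N2O campaign means within
#' `pulse_window_days` after a fertilization date are elevated by
#' `n2o_pulse_amplitude` with exponential decay (e-folding time one third of
#' the window).
#'
#' @param n_replicates_mineral,n_replicates_peat replicate counts per soil.
#' @param n_campaigns_mineral,n_campaigns_peat campaign counts per soil
#'   (>= 2), evenly spaced over `span_days`.
#' @param mean_sr_mineral true mean mineral-soil respiration, mgC m-2 h-1.
#' @param peat_ratio peat/mineral SR ratio, > 0.
#' @param mean_ch4 true mean soil CH4 flux, µgC m-2 h-1 (signed).
#' @param n2o_baseline baseline soil N2O flux, µgN m-2 h-1.
#' @param n2o_pulse_amplitude added N2O flux at a fertilization date,
#'   µgN m-2 h-1.
#' @param fertilization_dates `Date` vector of fertilizer applications (may be
#'   empty for an unfertilized stand).
#' @param pulse_window_days length of the post-fertilization pulse window.
#' @param dispersion coefficient of variation of all draws, >= 0.
#' @param seed integer RNG seed.
#' @param start_date first campaign date.
#' @param span_days period over which campaigns are spread.
#' @return a validated `chamber_sim_params` list.
#' @export
chamber_sim_params <- function(n_replicates_mineral = 4L,
                               n_replicates_peat = 2L,
                               n_campaigns_mineral = 45L,
                               n_campaigns_peat = 37L,
                               mean_sr_mineral = 91.7,
                               peat_ratio = 2.6,
                               mean_ch4 = -15,
                               n2o_baseline = 10,
                               n2o_pulse_amplitude = 0,
                               fertilization_dates = as.Date(character()),
                               pulse_window_days = 14,
                               dispersion = 0.4,
                               seed = 1L,
                               start_date = as.Date("2014-06-01"),
                               span_days = 365) {
  if (n_campaigns_mineral < 2 || n_campaigns_peat < 2) {
    stop("at least two campaigns are required per soil type", call. = FALSE)
  }
  if (peat_ratio <= 0) stop("`peat_ratio` must be > 0", call. = FALSE)
  if (dispersion < 0) stop("`dispersion` must be >= 0", call. = FALSE)
  structure(
    list(
      n_replicates_mineral = as.integer(n_replicates_mineral),
      n_replicates_peat = as.integer(n_replicates_peat),
      n_campaigns_mineral = as.integer(n_campaigns_mineral),
      n_campaigns_peat = as.integer(n_campaigns_peat),
      mean_sr_mineral = mean_sr_mineral, peat_ratio = peat_ratio,
      mean_ch4 = mean_ch4, n2o_baseline = n2o_baseline,
      n2o_pulse_amplitude = n2o_pulse_amplitude,
      fertilization_dates = as.Date(fertilization_dates),
      pulse_window_days = pulse_window_days,
      dispersion = dispersion, seed = as.integer(seed),
      start_date = as.Date(start_date), span_days = span_days
    ),
    class = "chamber_sim_params"
  )
}

#' Chamber campaign flux table
#'
#' Container for dated spot fluxes from static-chamber campaigns: one row per
#' replicate x campaign x gas, with per-gas units mgC m-2 h-1 (CO2),
#' µgC m-2 h-1 (CH4) and µgN m-2 h-1 (N2O).
#'
#' @param entries data.frame with columns `date` (`Date`), `replicate`
#'   (character), `soil_type` (`"mineral"`/`"peat"`), `gas`
#'   (`"CO2"`/`"CH4"`/`"N2O"`), `flux` (numeric).
#' @return a `chamber_campaign_set`.
#' @export
chamber_campaign_set <- function(entries) {
  need <- c("date", "replicate", "soil_type", "gas", "flux")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(entries$soil_type %in% c("mineral", "peat"))) {
    stop("soil_type must be 'mineral' or 'peat'", call. = FALSE)
  }
  if (!all(entries$gas %in% c("CO2", "CH4", "N2O"))) {
    stop("gas must be CO2, CH4 or N2O", call. = FALSE)
  }
  entries$date <- as.Date(entries$date)
  structure(list(entries = entries), class = "chamber_campaign_set")
}

#' @export
print.chamber_campaign_set <- function(x, ...) {
  e <- x$entries
  cat(sprintf(
    "<chamber_campaign_set> %d flux values, %d campaign dates, gases: %s\n",
    nrow(e), length(unique(e$date)), paste(sort(unique(e$gas)), collapse = "/")
  ))
  invisible(x)
}

# lognormal draws with arithmetic mean m and coefficient of variation cv
.rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

.rnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  stats::rnorm(n, m, abs(m) * cv)
}

#' Simulate static-chamber campaigns
#'
#' Draws one flux value per replicate x campaign x gas. Peat soil-respiration
#' draws use mean `mean_sr_mineral` x `peat_ratio`; N2O campaign means are
#' elevated after fertilization dates (exponentially decaying pulse within the
#' configured window). Deterministic under a fixed seed.
#'
#' @param params a [chamber_sim_params()].
#' @return a [chamber_campaign_set()].
#' @export
gen_chamber_campaigns <- function(params) {
  stopifnot(inherits(params, "chamber_sim_params"))
  set.seed(params$seed)
  cv <- params$dispersion
  soil_block <- function(soil, n_rep, n_camp, sr_mean) {
    dates <- params$start_date +
      round(seq(0, params$span_days, length.out = n_camp))
    reps <- paste0(toupper(substr(soil, 1, 1)), seq_len(n_rep))
    grid <- expand.grid(replicate = reps, date = dates,
                        stringsAsFactors = FALSE)
    nn <- nrow(grid)
    # N2O expected value per campaign date: baseline + decaying pulse
    n2o_mean <- rep(params$n2o_baseline, length(dates))
    for (fd in as.list(params$fertilization_dates)) {
      dt <- as.numeric(dates - fd)
      in_win <- dt >= 0 & dt <= params$pulse_window_days
      tau <- params$pulse_window_days / 3
      n2o_mean[in_win] <- n2o_mean[in_win] +
        params$n2o_pulse_amplitude * exp(-dt[in_win] / tau)
    }
    n2o_by_row <- n2o_mean[match(grid$date, dates)]
    rbind(
      data.frame(grid, soil_type = soil, gas = "CO2",
                 flux = .rlnorm_mean_cv(nn, sr_mean, cv)),
      data.frame(grid, soil_type = soil, gas = "CH4",
                 flux = .rnorm_mean_cv(nn, params$mean_ch4, cv)),
      data.frame(grid, soil_type = soil, gas = "N2O",
                 flux = if (cv == 0) n2o_by_row else
                   stats::rnorm(nn, n2o_by_row, abs(n2o_by_row) * cv))
    )
  }
  entries <- rbind(
    soil_block("mineral", params$n_replicates_mineral,
               params$n_campaigns_mineral, params$mean_sr_mineral),
    soil_block("peat", params$n_replicates_peat,
               params$n_campaigns_peat,
               params$mean_sr_mineral * params$peat_ratio)
  )
  entries <- entries[, c("date", "replicate", "soil_type", "gas", "flux")]
  rownames(entries) <- NULL
  chamber_campaign_set(entries)
}

#' Fixture foreground LCA inventories
#'
#' Returns a complete foreground inventory for the LCA engine: the process
#' parameters of the palm-oil energy chain plus per-stage background emission
#' factors, mill by-product fractions, POME methane inventory and the fossil
#' reference. Two profiles are shipped:
#'
#' * `"paper_defaults"` — process parameters at their field-standard values
#'   (FFB:CPO 5.18, 95% biodiesel yield, heating values 37.5 / 16 MJ kg-1,
#'   ...) and representative literature-magnitude background factors. The
#'   background factors are fixture values: absolute per-MJ totals computed
#'   from this profile are inventory-dependent and only component structure is
#'   meaningful.
#' * `"zero_background"` — same process parameters with every background
#'   emission factor (and the POME inventory) set to zero; useful for
#'   conservation tests.
#'
#' @param profile fixture name.
#' @return a `foreground_inventory` list with elements `process`
#'   (a [process_params()]), `background` (named factors), `mill_allocation`,
#'   `pome_ch4_inventory` (gCH4 per MJ biodiesel) and `fossil_reference`
#'   (gCO2-eq MJ-1).
#' @export
make_fixture_inventory <- function(profile = c("paper_defaults",
                                               "zero_background")) {
  if (!is.character(profile) || length(profile) != 1L ||
      !profile %in% c("paper_defaults", "zero_background")) {
    stop("unknown inventory profile: ", paste(profile, collapse = ","),
         call. = FALSE)
  }
  background <- list(
    ef_fert_n = 3300,      # gCO2-eq per kg N, fertilizer production
    ef_fert_k = 550,       # gCO2-eq per kg K
    ef_fert_p = 1100,      # gCO2-eq per kg P
    ef_glyphosate = 10,    # gCO2-eq per ml formulated product
    n2o_field_fraction = 0.01, # kg N2O-N emitted per kg N applied
    ef_transport = 0.12,   # gCO2-eq per kg-km, truck
    ef_milling = 25,       # gCO2-eq per kg FFB processed
    ef_transesterification = 250, # gCO2-eq per kg biodiesel
    fibre_fraction_ffb = 0.13,    # kg fibre per kg FFB
    shell_fraction_ffb = 0.065    # kg shell per kg FFB
  )
  pome <- 1.8 / (44 / 16) # gCH4 MJ-1 such that closed-system POME = 1.8 gCO2-eq MJ-1
  if (profile == "zero_background") {
    background[c("ef_fert_n", "ef_fert_k", "ef_fert_p", "ef_glyphosate",
                 "n2o_field_fraction", "ef_transport", "ef_milling",
                 "ef_transesterification")] <- 0
    pome <- 0
  }
  structure(
    list(
      profile = profile,
      process = process_params(),
      background = background,
      mill_allocation = 1.0,
      pome_ch4_inventory = pome,
      fossil_reference = 94
    ),
    class = "foreground_inventory"
  )
}
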