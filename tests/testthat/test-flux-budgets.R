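make_constant_series <- function(value, n = 48 * 31, start = "2014-01-01") {
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            by = 1800, length.out = n)
  flux_series(ts, rep(value, n), unit = "umol_m2_s")
}

test_that("gap-filling is the identity on gap-free series and exact on constants", {
  s <- make_constant_series(2)
  expect_identical(gapfill_diurnal(s), s)
  gappy <- s
  set.seed(1)
  idx <- sample(nrow(s), round(0.2 * nrow(s)))
  gappy$flux[idx] <- NA
  gappy$qc[idx] <- 1L
  filled <- gapfill_diurnal(gappy)
  expect_equal(filled$flux, s$flux)
  expect_true(all(filled$qc[idx] == 2L))
  # originals untouched
  expect_equal(filled$flux[-idx], s$flux[-idx])
})

test_that("gap-filling a gappy diurnal series recovers the integral within 5%", {
  clean <- gen_halfhourly_nee(nee_sim_params(1012, months_covered = 8,
                                             seed = 9L))
  ref <- integrate_annual_nee(clean)
  gappy <- gen_halfhourly_nee(nee_sim_params(1012, months_covered = 8,
                                             gap_fraction = 0.2,
                                             noise_sd = 0.05, seed = 9L))
  est <- integrate_annual_nee(gapfill_diurnal(gappy))
  expect_lt(abs(est - ref) / abs(ref), 0.05)
})

test_that("gap-filling refuses series with at least 50% gaps", {
  s <- make_constant_series(1, n = 480)
  s$flux[1:240] <- NA
  s$qc[1:240] <- 1L
  expect_error(gapfill_diurnal(s), "50%")
})

test_that("annual integration converts units, requires whole months and extrapolates 12/m", {
  # 12-month constant series: identity on its own total
  n <- 48 * 365
  ts <- seq(as.POSIXct("2014-01-01 00:00:00", tz = "UTC"), by = 1800,
            length.out = n)
  target <- -754
  per_slot <- target / n # gC per half-hour
  s <- flux_series(ts, rep(per_slot, n), unit = "gC_hh")
  expect_equal(integrate_annual_nee(s), -754, tolerance = 1e-10)
  # 8-month series summing to 674.7 -> x 12/8
  n8 <- 48 * (31 + 28 + 31 + 30 + 31 + 30 + 31 + 31)
  ts8 <- ts[1:n8]
  s8 <- flux_series(ts8, rep(674.7 / n8, n8), unit = "gC_hh")
  expect_equal(integrate_annual_nee(s8), 674.7 * 12 / 8, tolerance = 1e-9)
  expect_equal(integrate_annual_nee(s8), 1012.05, tolerance = 1e-9)
  # partial months refused
  s_part <- flux_series(ts[1:100], rep(1, 100), unit = "gC_hh")
  expect_error(integrate_annual_nee(s_part), "month")
  # gaps refused
  sg <- s
  sg$flux[5] <- NA
  sg$qc[5] <- 1L
  expect_error(integrate_annual_nee(sg), "gap")
  expect_error(flux_series(ts[c(1, 3)], c(1, 1)), "half-hour")
})

test_that("trapezoidal annualization matches hand-computed campaign layouts", {
  mk <- function(dates, fluxes, gas = "CO2", soil = "mineral") {
    chamber_campaign_set(data.frame(
      date = as.Date(dates), replicate = "R1", soil_type = soil,
      gas = gas, flux = fluxes
    ))
  }
  # constant 100 mg at year start and end -> 100 mg x 8760 h = 876 g
  cc <- mk(c("2014-01-01", "2015-01-01"), c(100, 100))
  expect_equal(trapezoid_annual(cc, "CO2", "mineral"), 876)
  # linear 0 -> 200 over the year: mean 100 mg
  cc2 <- mk(c("2014-01-01", "2015-01-01"), c(0, 200))
  expect_equal(trapezoid_annual(cc2, "CO2", "mineral"), 876)
  # all-zero fluxes
  cc0 <- mk(c("2014-01-01", "2014-06-01", "2015-01-01"), c(0, 0, 0))
  expect_equal(trapezoid_annual(cc0, "CO2", "mineral"), 0)
  # constant-flux invariance to schedule, incl. edge extension
  for (sched in list(c("2014-02-10", "2014-07-01", "2014-11-20"),
                     c("2014-01-01", "2014-01-15"))) {
    ccs <- mk(sched, rep(50, length(sched)))
    expect_equal(trapezoid_annual(ccs, "CO2", "mineral",
                                  year_start = as.Date("2014-01-01")),
                 50 * 8760 / 1000)
  }
  # per-gas microgram units
  ch4 <- mk(c("2014-01-01", "2015-01-01"), c(-15, -15), gas = "CH4")
  expect_equal(trapezoid_annual(ch4, "CH4", "mineral"), -15 * 8760 / 1e6)
  # replicate means are taken before integration
  cc_rep <- chamber_campaign_set(data.frame(
    date = as.Date(rep(c("2014-01-01", "2015-01-01"), each = 2)),
    replicate = c("R1", "R2", "R1", "R2"), soil_type = "mineral",
    gas = "CO2", flux = c(80, 120, 90, 110)
  ))
  expect_equal(trapezoid_annual(cc_rep, "CO2", "mineral"), 876)
  # single campaign refused
  cc1 <- mk("2014-06-01", 100)
  expect_error(trapezoid_annual(cc1, "CO2", "mineral"), "two campaigns")
})

test_that("NEP arithmetic and sign conventions are exact", {
  expect_equal(nep(1012, 0), 1012)
  expect_equal(nep(0, 0), 0)
  expect_equal(nep(-799, 1039), 240)
  expect_error(nep(0, -1), "non-negative")
})

test_that("soil-respiration substitution identities hold for peat and second rotation", {
  expect_equal(nee_peat(-754, 803, 803), -754) # identity
  expect_equal(nee_peat(-754, 803, 2088), 531)
  expect_equal(nee_peat(0, 0, 100), 100)
  expect_equal(nee_second_rotation(-754, 803, 803), -754)
  expect_equal(nee_second_rotation(-754, 803, 742), -815)
  # lower substituted respiration lowers NEE
  expect_lt(nee_second_rotation(-754, 803, 700), -754)
  expect_error(nee_peat(0, -1, 0), "non-negative")
})

test_that("GWP_net combines the three gases with the fixed conversion constants", {
  expect_equal(gwp_net(0, 0, 0), 0)
  # 240*3.664 - 0.13*(16/12)*25 + 0.33*(44/28)*298, each term by hand
  expect_equal(gwp_net(240, -0.13, 0.33),
               879.36 - 4.333333 + 154.5343, tolerance = 1e-6)
  expect_equal(gwp_net(52, -0.13, 0.33), 340.729, tolerance = 1e-3)
  k <- gwp_constants()
  expect_equal(k$c_to_co2, 3.664)
  expect_equal(k$gwp_ch4, 25)
  expect_equal(k$gwp_n2o, 298)
})

test_that("GHGI divides by yield in g m-2 and is undefined at zero yield", {
  expect_equal(round(ghgi(gwp_net(240, -0.13, 0.33), 26.5), 1), 0.4)
  expect_equal(round(ghgi(gwp_net(52, -0.13, 0.33), 26.5), 1), 0.1)
  expect_equal(ghgi(0, 26.5), 0)
  expect_error(ghgi(100, 0), "undefined")
})

test_that("annual budgets satisfy their internal identities", {
  b <- annual_budget(nee = -799, cyield = 1039, ch4 = -0.13, n2o = 0.33,
                     yield = 26.5)
  expect_equal(b$nep, b$nee + b$cyield)
  expect_equal(b$gwp_net, gwp_net(b$nep, b$ch4, b$n2o))
  expect_equal(b$ghgi, b$gwp_net / 2650)
  b0 <- annual_budget(nee = 1012)
  expect_equal(b0$nep, 1012) # no harvest: NEP equals NEE
  expect_true(is.na(b0$ghgi))
})
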