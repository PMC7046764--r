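#' Read and write flux series as delimited text
#'
#' Flux series are stored as comma-separated text with ISO-8601 UTC
#' timestamps, one row per half-hour record, preceded by `#` header lines
#' documenting the columns and declaring the flux unit.
#'
#' @param x a [flux_series()].
#' @param path file path.
#' @return `write_flux_series` returns `path` invisibly; `read_flux_series`
#'   returns a [flux_series()].
#' @export
write_flux_series <- function(x, path) {
  stopifnot(inherits(x, "flux_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# half-hourly ecosystem flux series",
    "# columns: timestamp (ISO-8601 UTC, slot start), flux, qc (0 measured / 1 gap / 2 filled)",
    paste0("# unit: ", flux_unit(x))
  ), con)
  out <- data.frame(
    timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
    flux = x$flux, qc = x$qc
  )
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flux_series
#' @export
read_flux_series <- function(path) {
  hdr <- readLines(path, n = 10)
  unit_line <- grep("^# unit:", hdr, value = TRUE)
  if (length(unit_line) == 0L) stop("missing '# unit:' header", call. = FALSE)
  unit <- trimws(sub("^# unit:", "", unit_line[1]))
  d <- utils::read.csv(path, comment.char = "#")
  ts <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  flux_series(ts, d$flux, d$qc, unit = unit)
}

#' Read and write chamber campaign sets as delimited text
#'
#' One row per replicate x campaign x gas, with per-gas units documented in
#' the header (CO2 in mgC m-2 h-1, CH4 in µgC m-2 h-1, N2O in µgN m-2 h-1).
#'
#' @param x a [chamber_campaign_set()].
#' @param path file path.
#' @export
write_chamber_set <- function(x, path) {
  stopifnot(inherits(x, "chamber_campaign_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# static-chamber campaign fluxes",
    "# columns: date (ISO-8601), replicate, soil_type, gas, flux",
    "# units: CO2 mgC m-2 h-1, CH4 ugC m-2 h-1, N2O ugN m-2 h-1"
  ), con)
  utils::write.table(x$entries, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_chamber_set
#' @export
read_chamber_set <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  chamber_campaign_set(d)
}

#' Read and write foreground inventories as YAML
#'
#' @param inventory a foreground inventory list (see
#'   [make_fixture_inventory()]).
#' @param path file path.
#' @export
write_inventory <- function(inventory, path) {
  x <- unclass(inventory)
  x$process <- unclass(x$process)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_inventory
#' @export
read_inventory <- function(path) {
  x <- yaml::read_yaml(path)
  x$process <- do.call(process_params, x$process)
  structure(x, class = "foreground_inventory")
}

#' Write an annual budget as a one-row delimited record
#'
#' @param budget an [annual_budget()].
#' @param path file path.
#' @export
write_annual_budget <- function(budget, path) {
  stopifnot(inherits(budget, "annual_budget"))
  utils::write.csv(as.data.frame(budget), path, row.names = FALSE)
  invisible(path)
}
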