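#' Process parameters of the palm-oil energy chain
#'
#' Physical parameters of the mill and transesterification stages: the
#' fresh-fruit-bunch (FFB) to crude palm oil (CPO) ratio, the biodiesel yield
#' from CPO, heating values used for energy allocation, carbon and water
#' contents of the combusted products and transport distances.
#'
#' @param ffb_per_cpo kg FFB needed per kg CPO.
#' @param biodiesel_fraction_of_cpo mass fraction of CPO converted to
#'   biodiesel (the remainder leaves as glycerol).
#' @param hv_biodiesel,hv_glycerol lower heating values, MJ kg-1.
#' @param biodiesel_c_content carbon mass fraction of biodiesel.
#' @param fibre_water,shell_water water mass fractions of mill fibre and
#'   shell.
#' @param fibre_c,shell_c carbon mass fractions (of fresh mass basis applied
#'   after water correction).
#' @param cpo_transport_km CPO transport distance to the biodiesel plant, km.
#' @param mill_distance_km FFB transport distance to the mill, km.
#' @return a validated `process_params` list.
#' @export
process_params <- function(ffb_per_cpo = 5.18,
                           biodiesel_fraction_of_cpo = 0.95,
                           hv_biodiesel = 37.5, hv_glycerol = 16,
                           biodiesel_c_content = 0.7635,
                           fibre_water = 0.40, shell_water = 0.35,
                           fibre_c = 0.472, shell_c = 0.524,
                           cpo_transport_km = 250, mill_distance_km = 25) {
  fracs <- c(biodiesel_fraction_of_cpo, biodiesel_c_content, fibre_water,
             shell_water, fibre_c, shell_c)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions must be in [0, 1]", call. = FALSE)
  }
  if (hv_biodiesel <= 0 || hv_glycerol <= 0) {
    stop("heating values must be > 0", call. = FALSE)
  }
  structure(
    list(
      ffb_per_cpo = ffb_per_cpo,
      biodiesel_fraction_of_cpo = biodiesel_fraction_of_cpo,
      hv_biodiesel = hv_biodiesel, hv_glycerol = hv_glycerol,
      biodiesel_c_content = biodiesel_c_content,
      fibre_water = fibre_water, shell_water = shell_water,
      fibre_c = fibre_c, shell_c = shell_c,
      cpo_transport_km = cpo_transport_km,
      mill_distance_km = mill_distance_km
    ),
    class = "process_params"
  )
}

#' Land-use-change parameters
#'
#' Carbon stocks of the reference land use (forest) and the actual land use
#' (plantation), the amortization period, and the forest NEE basis for
#' foregone sequestration.
#'
#' @param cs_r reference (forest) carbon stock, MgC ha-1.
#' @param cs_a actual (plantation) carbon stock, MgC ha-1.
#' @param T amortization period (plantation life cycle), years, > 0.
#' @param forest_nee NEE the forest would have sustained, gC m-2 yr-1
#'   (negative = the forest was a sink).
#' @return a `luc_params` list.
#' @export
luc_params <- function(cs_r = 283.5, cs_a = 109.9, T = 25,
                       forest_nee = -124) {
  if (T <= 0) stop("`T` must be > 0", call. = FALSE)
  structure(
    list(cs_r = cs_r, cs_a = cs_a, T = T, forest_nee = forest_nee),
    class = "luc_params"
  )
}

#' Annualized land-use-change emissions
#'
#' E_LU = ((CS_R - CS_A) / T) x 3.664: the carbon-stock loss from conversion,
#' amortized over the plantation life cycle and converted to CO2.
#'
#' @param p a [luc_params()].
#' @return list with the annualized emission in both common unit systems:
#'   `mg_per_ha` (MgCO2 ha-1 yr-1) and `g_per_m2` (gCO2-eq m-2 yr-1).
#' @export
luc_annualized <- function(p) {
  stopifnot(inherits(p, "luc_params"))
  mg_ha <- (p$cs_r - p$cs_a) / p$T * gwp_constants()$c_to_co2
  list(mg_per_ha = mg_ha, g_per_m2 = mg_ha * 100)
}

#' Foregone forest sequestration
#'
#' The CO2 uptake the pre-conversion forest would have continued to provide,
#' charged to the plantation system as a positive emission:
#' `-forest_nee x 3.664`.
#'
#' @param forest_nee forest NEE, gC m-2 yr-1 (negative = sink, giving a
#'   positive charge).
#' @return gCO2-eq m-2 yr-1.
#' @export
foregone_sequestration <- function(forest_nee) {
  -forest_nee * gwp_constants()$c_to_co2
}

#' Mass and energy flows of the palm-oil energy chain
#'
#' Per-hectare annual product flows from an FFB yield trajectory: CPO mass
#' (FFB / ffb_per_cpo), biodiesel and glycerol masses (95% / 5% of CPO by
#' default) and their energy contents via the heating values.
#'
#' @param yield_traj an [annual_trajectory()] of FFB yield, Mg ha-1 yr-1.
#' @param p a [process_params()].
#' @return data.frame with one row per age: `ffb_kg`, `cpo_kg`,
#'   `biodiesel_kg`, `glycerol_kg`, `biodiesel_mj`, `glycerol_mj` (all per
#'   ha).
#' @export
energy_chain <- function(yield_traj, p = process_params()) {
  ffb <- as.numeric(yield_traj) * 1000
  if (any(ffb < 0)) stop("yield must be non-negative", call. = FALSE)
  cpo <- ffb / p$ffb_per_cpo
  bd <- cpo * p$biodiesel_fraction_of_cpo
  gly <- cpo * (1 - p$biodiesel_fraction_of_cpo)
  data.frame(
    age = seq_along(ffb),
    ffb_kg = ffb, cpo_kg = cpo, biodiesel_kg = bd, glycerol_kg = gly,
    biodiesel_mj = bd * p$hv_biodiesel, glycerol_mj = gly * p$hv_glycerol
  )
}

#' Co-product allocation factors
#'
#' Distributes a process's emissions among its co-products, either by energy
#' content (the default in the LCA engine) or by economic revenue.
#'
#' @param method `"energy"` or `"economic"`.
#' @param outputs named numeric vector: energy content (MJ) per product for
#'   the energy method, or output mass per product for the economic method.
#' @param prices named numeric vector of prices per unit mass (same names as
#'   `outputs`); required for the economic method.
#' @return named factors summing to 1.
#' @export
allocation_factor <- function(method = c("energy", "economic"), outputs,
                              prices = NULL) {
  method <- match.arg(method)
  if (length(outputs) < 1L) stop("at least one co-product required", call. = FALSE)
  if (method == "energy") {
    return(outputs / sum(outputs))
  }
  if (is.null(prices)) {
    stop("economic allocation requires `prices`", call. = FALSE)
  }
  rev <- outputs * prices[names(outputs)]
  rev / sum(rev)
}

#' Biogenic CO2 from product combustion
#'
#' CO2 released when a biomass product is burned, accounting for its water
#' and carbon content: `mass x (1 - water) x c_content x 3.664`, in grams.
#' For biodiesel use `water_content = 0`.
#'
#' @param mass_kg combusted mass, kg.
#' @param c_content carbon mass fraction in [0, 1].
#' @param water_content water mass fraction in [0, 1] (0 for biodiesel).
#' @return gCO2.
#' @export
biogenic_combustion <- function(mass_kg, c_content, water_content = 0) {
  if (any(c_content < 0 | c_content > 1) ||
      any(water_content < 0 | water_content > 1)) {
    stop("fractions must be in [0, 1]", call. = FALSE)
  }
  mass_kg * 1000 * (1 - water_content) * c_content * gwp_constants()$c_to_co2
}

#' Palm-oil-mill-effluent emissions
#'
#' Methane produced by anaerobic POME degradation, per MJ of biodiesel. In a
#' closed system the CH4 is captured and combusted, leaving only its CO2
#' (x 44/16); dumped in an open lagoon it escapes unburned and counts at its
#' full GWP of 25. The open/closed ratio is 25 / (44/16) = 9.09, the
#' "ninefold" penalty of open lagoons, independent of the inventory.
#'
#' @param mode `"closed"` (captured and burned) or `"open"` (vented lagoon).
#' @param ch4_inventory CH4 generated per MJ biodiesel, gCH4 MJ-1, >= 0.
#' @return gCO2-eq MJ-1.
#' @export
pome_emissions <- function(mode = c("closed", "open"), ch4_inventory) {
  mode <- match.arg(mode)
  if (any(ch4_inventory < 0)) stop("`ch4_inventory` must be >= 0", call. = FALSE)
  if (mode == "closed") ch4_inventory * 44 / 16
  else ch4_inventory * gwp_constants()$gwp_ch4
}

#' Assemble a per-MJ life-cycle GHG result
#'
#' Runs the full life-cycle computation for one scenario: sums component
#' emissions per hectare over the whole rotation cycle, divides by the
#' cycle-total biodiesel energy, and applies energy allocation between
#' biodiesel and glycerol. In `"enhanced"` mode the measured ecosystem fluxes
#' enter as a (normally negative) ecosystem-sink component and the biogenic
#' CO2 from burning biodiesel, fibre and shell is counted; `"traditional"`
#' mode zeroes both (the carbon-neutrality assumption). Second-rotation
#' scenarios carry no land-use-change or foregone-sequestration charge.
#'
#' Components (all gCO2-eq per MJ biodiesel):
#' * `ecosystem_sink` — cumulative NEE plus soil CH4 as CO2-eq (enhanced
#'   only).
#' * `cultivation` — fertilizer and herbicide production, field N2O induced
#'   by applied N, and FFB transport to the mill.
#' * `milling` — mill processing per kg FFB.
#' * `biodiesel_production` — transesterification inputs and CPO transport.
#' * `pome` — closed-system POME methane combustion.
#' * `biogenic_use` — CO2 from burning biodiesel, fibre and shell (enhanced
#'   only).
#' * `luc` — annualized land-use-change emissions (first rotation only).
#' * `foregone_sequestration` — forest uptake foregone (first rotation only).
#'
#' @param spec a [scenario_spec()].
#' @param inventory a [make_fixture_inventory()] (or compatible) foreground
#'   inventory.
#' @param trajs optional named list of trajectories (`nee`, `yield`, `n`,
#'   `k`, `p`, `glyphosate`); any missing entry is built from `spec` (a
#'   `decay` curve is then required for second-rotation NEE).
#' @param luc a [luc_params()]; defaults to the measured carbon stocks
#'   amortized over `spec$cycle_length`.
#' @param mode `"enhanced"` or `"traditional"`.
#' @param fossil_reference fossil comparator, gCO2-eq MJ-1; defaults to the
#'   inventory's value.
#' @param decay optional [calibrate_decay()] curve for second-rotation NEE.
#' @return an `lca_result`: list with `components` (named numeric,
#'   gCO2-eq MJ-1), `net`, `allocation_factor`, `mode`, `rotation`,
#'   `savings_vs_fossil`, `total_biodiesel_mj_per_ha` and `scenario`.
#' @export
assemble_lca <- function(spec, inventory, trajs = list(), luc = NULL,
                         mode = c("enhanced", "traditional"),
                         fossil_reference = NULL, decay = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  mode <- match.arg(mode)
  p <- inventory$process
  bg <- inventory$background
  needed_bg <- c("ef_fert_n", "ef_fert_k", "ef_fert_p", "ef_glyphosate",
                 "n2o_field_fraction", "ef_transport", "ef_milling",
                 "ef_transesterification", "fibre_fraction_ffb",
                 "shell_fraction_ffb")
  missing_bg <- setdiff(needed_bg, names(bg))
  if (length(missing_bg)) {
    stop("incomplete inventory; missing background factor(s): ",
         paste(missing_bg, collapse = ", "), call. = FALSE)
  }
  if (is.null(fossil_reference)) fossil_reference <- inventory$fossil_reference
  if (is.null(luc)) luc <- luc_params(T = spec$cycle_length)

  if (is.null(trajs$yield)) trajs$yield <- yield_trajectory(spec)
  if (is.null(trajs$nee)) trajs$nee <- nee_trajectory(spec, decay = decay)
  inp <- input_trajectories(spec)
  for (s in names(inp)) if (is.null(trajs[[s]])) trajs[[s]] <- inp[[s]]
  if (length(trajs$nee) != spec$cycle_length ||
      length(trajs$yield) != spec$cycle_length) {
    stop("trajectories must cover the full cycle", call. = FALSE)
  }

  en <- energy_chain(trajs$yield, p)
  total_bd_mj <- sum(en$biodiesel_mj)
  total_gly_mj <- sum(en$glycerol_mj)
  if (total_bd_mj <= 0) stop("scenario produces no biodiesel energy", call. = FALSE)
  alloc <- as.numeric(allocation_factor(
    "energy", c(biodiesel = total_bd_mj, glycerol = total_gly_mj)
  )["biodiesel"])

  k <- gwp_constants()
  # per-ha cycle totals, gCO2-eq ha-1
  n_kg <- as.numeric(trajs$n); k_kg <- as.numeric(trajs$k)
  p_kg <- as.numeric(trajs$p); gly_ml <- as.numeric(trajs$glyphosate)
  field_n2o <- sum(n_kg) * bg$n2o_field_fraction * k$n2o_n_to_n2o *
    k$gwp_n2o * 1000 # kg N2O-N -> g CO2-eq
  cultivation <- sum(n_kg) * bg$ef_fert_n + sum(k_kg) * bg$ef_fert_k +
    sum(p_kg) * bg$ef_fert_p + sum(gly_ml) * bg$ef_glyphosate +
    field_n2o + sum(en$ffb_kg) * p$mill_distance_km * bg$ef_transport
  milling <- sum(en$ffb_kg) * bg$ef_milling
  mill_alloc <- if (is.null(inventory$mill_allocation)) 1 else
    inventory$mill_allocation
  cultivation <- cultivation * mill_alloc
  milling <- milling * mill_alloc
  production <- sum(en$biodiesel_kg) * bg$ef_transesterification +
    sum(en$cpo_kg) * p$cpo_transport_km * bg$ef_transport
  pome <- pome_emissions("closed", inventory$pome_ch4_inventory) * total_bd_mj

  if (mode == "enhanced") {
    sink <- (sum(as.numeric(trajs$nee)) * k$c_to_co2 +
               spec$soil_ch4 * spec$cycle_length * k$ch4_c_to_ch4 *
                 k$gwp_ch4) * 1e4 # gC m-2 -> gCO2-eq ha-1
    biogenic <- sum(biogenic_combustion(en$biodiesel_kg,
                                        p$biodiesel_c_content)) +
      sum(biogenic_combustion(en$ffb_kg * bg$fibre_fraction_ffb,
                              p$fibre_c, p$fibre_water)) +
      sum(biogenic_combustion(en$ffb_kg * bg$shell_fraction_ffb,
                              p$shell_c, p$shell_water))
  } else {
    sink <- 0
    biogenic <- 0
  }
  if (spec$rotation == "first") {
    luc_total <- luc_annualized(luc)$g_per_m2 * spec$cycle_length * 1e4
    foregone <- foregone_sequestration(luc$forest_nee) *
      spec$cycle_length * 1e4
  } else {
    luc_total <- 0
    foregone <- 0
  }

  per_mj <- c(
    ecosystem_sink = sink, cultivation = cultivation, milling = milling,
    biodiesel_production = production, pome = pome, biogenic_use = biogenic,
    luc = luc_total, foregone_sequestration = foregone
  ) * alloc / total_bd_mj
  net <- sum(per_mj)
  structure(
    list(
      scenario = spec$name, rotation = spec$rotation, mode = mode,
      components = per_mj, net = net,
      allocation_factor = alloc,
      savings_vs_fossil = 1 - net / fossil_reference,
      fossil_reference = fossil_reference,
      total_biodiesel_mj_per_ha = total_bd_mj
    ),
    class = "lca_result"
  )
}

#' @export
print.lca_result <- function(x, ...) {
  cat(sprintf(
    "<lca_result> scenario %s, %s rotation, %s LCA\n",
    x$scenario, x$rotation, x$mode
  ))
  comp <- data.frame(
    component = names(x$components),
    gCO2eq_per_MJ = round(unname(x$components), 2)
  )
  print(comp, row.names = FALSE)
  cat(sprintf(
    "  net %.1f gCO2-eq MJ-1 (allocation %.3f); savings vs fossil (%.0f): %.0f%%\n",
    x$net, x$allocation_factor, x$fossil_reference,
    100 * x$savings_vs_fossil
  ))
  invisible(x)
}
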