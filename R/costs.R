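#' Default cost and constraint parameters
#'
#' All monetary values are 2010 US$.  The per-hectare cost of growing a crop
#' is a base cost (roughly a third of an intensive system's cost per
#' hectare, representing the minimum to produce at all) plus input costs
#' that are each the product of an intensity and a cost rate: fertiliser
#' ($/kgN), irrigation water ($/km3, scaled per cell by an aridity-driven
#' index), and management ($/ha at full intensity, carrying the remainder of
#' intensive-system costs).  Pasture has a low base cost representing
#' extensive grazing.  Conversion between natural and agricultural land, or
#' between cropland and pasture, costs a one-off amount per hectare
#' converted.  Import prices are inflated by tariff, transport and loss
#' rates; irrigation efficiency eta is the ratio of crop water requirement
#' to water withdrawn.
#'
#' @param ... named overrides of any default element.
#' @return list of class `cost_parameters`.
#' @export
default_costs <- function(...) {
  costs <- list(
    crop_base_cost = 200,          # $/ha/yr, minimum to produce
    mgmt_cost_rate = 400,          # $/ha/yr at management intensity 1
    fert_price = 1.0,              # $/kgN
    water_price_km3 = 5e7,         # $/km3 withdrawn, scaled by aridity index
    water_price_aridity_mult = 1,  # index = mult * (0.5 + aridity)
    pasture_base_cost = 30,        # $/ha/yr, extensive grazing
    irrigation_efficiency = 0.5,   # requirement / withdrawal
    conv_cost_nat_ag = 1000,       # $/ha converted, natural <-> agriculture
    conv_cost_crop_pasture = 250,  # $/ha converted, cropland <-> pasture
    tariff_rate = 0.10,
    transport_rate = 0.10,
    loss_rate = 0.05,
    fcr_monogastric = 4.0,         # t feed per t product
    fcr_ruminant = 7.0,            # t feed-equivalent per t product
    min_natural_frac = 0.05,       # per cell
    china_deforestation_cap = 0.011,  # fraction of forest area per yr
    export_price_floor = 0         # reserved; exports earn the world price
  )
  over <- list(...)
  bad <- setdiff(names(over), names(costs))
  if (length(bad)) stop("unknown cost parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  costs[names(over)] <- over
  stopifnot(costs$irrigation_efficiency > 0,
            costs$irrigation_efficiency <= 1,
            all(unlist(costs[c("crop_base_cost", "mgmt_cost_rate",
                               "fert_price", "water_price_km3",
                               "pasture_base_cost", "conv_cost_nat_ag",
                               "conv_cost_crop_pasture", "tariff_rate",
                               "transport_rate", "loss_rate")]) >= 0))
  structure(costs, class = "cost_parameters")
}

#' Per-cluster irrigation cost index
#'
#' Maps the dimensionless aridity index in \[0, 1\] monotonically to a water
#' price multiplier: arid places pay more per unit of water.
#'
#' @param aridity aridity index in \[0, 1\].
#' @param costs a `cost_parameters` list.
#' @return $ per km3 of water withdrawn.
#' @export
water_price <- function(aridity, costs) {
  costs$water_price_km3 * costs$water_price_aridity_mult * (0.5 + aridity)
}

#' Annual production cost of a cluster-level activity
#'
#' `area * (base + p_N F + p_W (irr_frac * requirement) / eta + mgmt_rate m)`
#' — the water charge is for withdrawal, i.e. the crop requirement divided
#' by the irrigation efficiency.
#'
#' @param area hectares.
#' @param fert fertiliser rate, kgN/ha.
#' @param irr_frac irrigation fraction of the full requirement, \[0, 1\].
#' @param mgmt management intensity, \[0, 1\].
#' @param irrig_req_km3_ha full-requirement water volume, km3/ha/yr.
#' @param aridity cell/cluster aridity index in \[0, 1\].
#' @param costs a `cost_parameters` list.
#' @param pasture logical (vectorised); pasture activities use the low
#'   extensive-grazing base cost.
#' @return cost in $/yr (0 at zero area).
#' @export
production_cost <- function(area, fert, irr_frac, mgmt, irrig_req_km3_ha,
                            aridity, costs, pasture = FALSE) {
  base <- ifelse(pasture, costs$pasture_base_cost, costs$crop_base_cost)
  per_ha <- base + costs$fert_price * fert +
    water_price(aridity, costs) * (irr_frac * irrig_req_km3_ha) /
      costs$irrigation_efficiency +
    costs$mgmt_cost_rate * mgmt
  area * per_ha
}

#' Livestock feed balance
#'
#' Monogastric livestock consume feed only: `feed_m = fcr_m * demand_m`.
#' Ruminant nutrition can come from a mix of pasture and feed:
#' `fcr_r * demand_r = pasture_output + feed_r`, both contributions
#' non-negative.
#'
#' @param ruminant_demand,monogastric_demand product tonnes/yr, >= 0.
#' @param pasture_output pasture dry matter available, t/yr.
#' @param fcr_ruminant,fcr_monogastric feed conversion ratios (t feed per t
#'   product).
#' @return list: `feed_monogastric`, `requirement_ruminant` (t feed-eq),
#'   `pasture_used`, `feed_ruminant`, all t/yr.
#' @export
livestock_balance <- function(ruminant_demand, monogastric_demand,
                              pasture_output, fcr_ruminant = 7,
                              fcr_monogastric = 4) {
  if (ruminant_demand < 0 || monogastric_demand < 0 || pasture_output < 0)
    stop("livestock demands and pasture output must be >= 0", call. = FALSE)
  req_r <- fcr_ruminant * ruminant_demand
  pasture_used <- min(pasture_output, req_r)
  list(feed_monogastric = fcr_monogastric * monogastric_demand,
       requirement_ruminant = req_r,
       pasture_used = pasture_used,
       feed_ruminant = req_r - pasture_used)
}
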