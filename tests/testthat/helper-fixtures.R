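# Shared fixtures, built once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = fixture_cache))
    assign(name, build(), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

fx_world_small <- function() fx("world_small", function()
  generate_world(2, 9, n_crops = 3, seed = 42))

fx_world_mid <- function() fx("world_mid", function()
  generate_world(3, 20, n_crops = 7, seed = 11))

fx_cfg_small <- function()
  default_config(world = list(n_countries = 2, cells_per_country = 9,
                              n_crops = 3),
                 years = list(start = 2010, end = 2016), seed = 7)

# a small spun-up state shared by driver and acceptance tests
fx_spun_small <- function() fx("spun_small", function() {
  w <- generate_world(2, 9, n_crops = 3, seed = 7)
  spin_up(initialise_simulation(w, fx_cfg_small()))
})

# short free-running scenario on the small world
fx_run_small <- function() fx("run_small", function()
  run_scenario(fx_cfg_small()))

# constant-drivers scenario: anchors, socio-economics and bioenergy all held
# at base-year values; used for stability audits
fx_run_constant <- function() fx("run_constant", function() {
  cfg <- default_config(world = list(n_countries = 3,
                                     cells_per_country = 12, n_crops = 7),
                        years = list(start = 2010, end = 2025),
                        bioenergy_constant = TRUE, seed = 3)
  w <- generate_world(3, 12, n_crops = 7, seed = 31)
  tr <- w$trajectories
  base <- tr[tr$year == 2010, ]
  tr$gdp_pc <- base$gdp_pc[match(tr$country_id, base$country_id)]
  tr$population <- base$population[match(tr$country_id, base$country_id)]
  w$trajectories <- tr
  run_scenario(cfg, world = w)
})

# Exhaustive coarse-lattice search over cluster intensities and demand
# splits; the independent optimality reference for small instances.
lattice_oracle <- function(clusters, surfaces, demand_t, costs,
                           splits = seq(0, 1, by = 0.05)) {
  tab <- clusters$table
  k <- nrow(tab)
  crop <- setdiff(unique(surfaces$crop), "pasture")[1]
  grid <- expand.grid(fert = c(0, 50, 100, 200, 400, 700, 1000),
                      irr = c(0, 0.5, 1), mgmt = c(0, 0.5, 1))
  cost_for <- function(j, q) {
    if (q <= 0) return(0)
    row <- tab[j, ]
    existing <- row[[paste0("area_", crop)]]
    req <- surfaces$irrig_req_km3_ha[
      match(paste(row$cluster_id, crop),
            paste(surfaces$cell_id, surfaces$crop))]
    best <- Inf
    for (i in seq_len(nrow(grid))) {
      y <- evaluate_yield(surfaces, row$cluster_id, crop, grid$fert[i],
                          grid$irr[i], grid$mgmt[i])
      if (y <= 0) next
      area <- q / y
      water <- grid$irr[i] * req * area / costs$irrigation_efficiency
      if (water > row$water_km3 + 1e-12) next
      exp_area <- max(0, area - existing)
      if (area > existing + row$avail_natural_ha + 1e-9) next
      cost <- production_cost(area, grid$fert[i], grid$irr[i], grid$mgmt[i],
                              req, row$aridity, costs) +
        exp_area * costs$conv_cost_nat_ag
      best <- min(best, cost)
    }
    best
  }
  if (k == 1) return(cost_for(1, demand_t))
  best <- Inf
  for (s in splits)
    best <- min(best, cost_for(1, s * demand_t) +
                  cost_for(2, (1 - s) * demand_t))
  best
}

# hand-built cluster set: two clusters, configurable anchor scaling, ample
# water; bypasses the generator so optimiser tests control every number
make_test_clusters <- function(yield_mult = c(1, 1), cropland_ha = c(1e5, 1e5),
                               pasture_ha = c(2e4, 2e4),
                               avail_natural_ha = c(2e5, 2e5),
                               water_km3 = c(10, 10), crops = "cereals_c3",
                               country_id = "T01") {
  k <- length(yield_mult)
  ids <- sprintf("%s_k%d", country_id, seq_len(k))
  tab <- data.frame(cluster_id = ids, country_id = country_id,
                    n_cells = 1L,
                    area_ha = cropland_ha + pasture_ha + avail_natural_ha +
                      1e5)
  for (cr in crops) tab[[paste0("area_", cr)]] <- cropland_ha / length(crops)
  tab$area_pasture <- pasture_ha
  tab$area_forest <- avail_natural_ha / 2 + 5e4
  tab$area_natural <- avail_natural_ha / 2 + 5e4
  tab$area_urban <- 0
  tab$avail_natural_ha <- avail_natural_ha
  tab$forest_ha <- tab$area_forest
  tab$pasture_yield <- 3
  tab$water_km3 <- water_km3
  tab$aridity <- 0.5
  anchors <- do.call(rbind, lapply(crops, function(cr)
    data.frame(cell_id = ids, crop = cr,
               y_n0_rf = 2 * yield_mult, y_n200_rf = 6 * yield_mult,
               y_n1000_rf = 8 * yield_mult,
               y_n0_ir = 2.6 * yield_mult, y_n200_ir = 7.8 * yield_mult,
               y_n1000_ir = 10.4 * yield_mult,
               irrig_req_km3_ha = 5e-6)))
  mem <- data.frame(cell_id = ids, cluster_id = ids)
  structure(list(membership = mem, table = tab, anchors = anchors,
                 min_natural_frac = 0.05),
            class = "agro_clusters")
}
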