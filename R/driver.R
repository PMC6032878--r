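#' Default scenario configuration
#'
#' Central parameter values for a scenario run: the simulated period, the
#' trailing yield-averaging window (5 years), the spin-up convergence
#' threshold (0.4% maximum relative change) and iteration cap, demand-model
#' settings, market settings (price adjustment rate, initial prices,
#' stocks-to-use ratio), yield-surface shapes including the 0.2%/yr
#' technology rate, cost overrides, and ensemble settings (n, half-width of
#' the uniform parameter perturbation).
#'
#' @param ... named overrides, merged recursively into the defaults.
#' @return a nested configuration list of class `scenario_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    world = list(n_countries = 3, cells_per_country = 20, n_crops = 7),
    years = list(start = 2010, end = 2030),
    yield_avg_window = 5,
    bioenergy_constant = FALSE,  # hold bioenergy demand at the base year
    spinup = list(threshold = 0.004, max_iter = 40),
    demand = list(history_years = 40, noise_sd = 0.08,
                  convergence_on = FALSE, convergence_rate = 1.0),
    market = list(
      lambda = 0.05, stocks_to_use = 0.2, prices_from_baseline = TRUE,
      prices = list(cereals = 200, oil_crops = 450, pulses = 400,
                    starchy_roots = 150, ruminant = 3000,
                    monogastric = 1800, energy_crops = 120)),
    surfaces = list(k_I = 2.0, g0 = 0.5, k_M = 2.0, tech_rate = 0.002),
    costs = list(),
    china_countries = character(),
    ensemble = list(n = 8, half_width = 0.5),
    seed = 1L
  )
  over <- list(...)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_rec(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_rec(cfg, over), class = "scenario_config")
}

sub_seed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2147483587L

subset_clusters <- function(clusters, country_id) {
  tab <- clusters$table[clusters$table$country_id == country_id, ]
  mem <- clusters$membership[clusters$membership$cluster_id %in%
                               tab$cluster_id, ]
  an <- clusters$anchors[clusters$anchors$cell_id %in% tab$cluster_id, ]
  structure(list(membership = mem, table = tab, anchors = an,
                 min_natural_frac = clusters$min_natural_frac),
            class = "agro_clusters")
}

#' Initialise the simulation state
#'
#' Fits the demand model on a generated history, clusters every country,
#' builds the water budget and cluster aggregates, fits cluster-level yield
#' surfaces and sets up the market.  Global trajectories (second-generation
#' bioenergy, initial stocks) are scaled by the ratio of the synthetic
#' world's land area to the real terrestrial land area so that the printed
#' global values remain meaningful at miniature scale.
#'
#' @param world an `agro_world`.
#' @param config a `scenario_config`.
#' @return a list of class `agro_state`.
#' @export
initialise_simulation <- function(world, config = default_config()) {
  stopifnot(inherits(world, "agro_world"))
  seed <- config$seed %||% 1L
  history <- generate_history(world, config$demand$history_years,
                              seed = sub_seed(seed, 2L),
                              noise_sd = config$demand$noise_sd)
  model <- fit_demand_model(history,
                            convergence_rate = config$demand$convergence_rate)
  costs <- do.call(default_costs, config$costs)
  membership <- do.call(rbind, lapply(world$countries$country_id,
    function(cid) cluster_country(world, cid, seed = sub_seed(seed, 3L))))
  water <- world_water_budget(world)
  clusters <- aggregate_clusters(world, membership, water,
                                 min_natural_frac = costs$min_natural_frac)
  sargs <- config$surfaces
  surfaces <- lapply(setNames(nm = world$countries$country_id), function(cid)
    cluster_surfaces(subset_clusters(clusters, cid), k_I = sargs$k_I,
                     g0 = sargs$g0, k_M = sargs$k_M,
                     tech_rate = sargs$tech_rate,
                     base_year = world$base_year))
  scale <- sum(world$cells$area_ha) / AGROSIM_REAL_LAND_HA

  comms <- world$commodities
  if ("energy_crops" %in% world$crops) comms <- c(comms, "energy_crops")
  prices <- unlist(config$market$prices)[comms]
  if (anyNA(prices)) stop("initial price missing for: ",
                          paste(comms[is.na(prices)], collapse = ", "))
  base_dem <- tapply(world$baseline_consumption$tonnes,
                     world$baseline_consumption$commodity, sum)
  stocks <- setNames(rep(0, length(comms)), comms)
  for (cm in names(base_dem))
    stocks[cm] <- config$market$stocks_to_use * base_dem[[cm]]
  if ("energy_crops" %in% comms)
    stocks["energy_crops"] <- config$market$stocks_to_use *
      bioenergy_demand(world$base_year)$secondgen_t * scale
  market <- market_state(prices, stocks, lambda = config$market$lambda)

  structure(list(world = world, model = model, costs = costs,
                 membership = membership, water = water,
                 clusters = clusters, surfaces = surfaces, market = market,
                 scale = scale, config = config, year = world$base_year,
                 solutions = NULL, spinup = NULL),
            class = "agro_state")
}

#' @export
print.agro_state <- function(x, ...) {
  cat("Simulation state at year", x$year, "-", nrow(x$clusters$table),
      "clusters,", length(x$surfaces), "countries\n")
  if (!is.null(x$spinup))
    cat(sprintf("  spin-up: %d iterations, terminal change %.3f%%%s\n",
                x$spinup$iterations, 100 * x$spinup$terminal_change,
                if (x$spinup$converged) "" else " (not converged)"))
  invisible(x)
}

country_base_demand <- function(world) {
  bio <- bioenergy_demand(world$base_year, world$baseline_firstgen)
  out <- lapply(setNames(nm = world$countries$country_id), function(cid) {
    d <- world$baseline_consumption[
      world$baseline_consumption$country_id == cid, ]
    v <- setNames(d$tonnes, d$commodity)
    fg <- bio$firstgen[bio$firstgen$country_id == cid, ]
    for (i in seq_len(nrow(fg)))
      v[fg$commodity[i]] <- v[fg$commodity[i]] + fg$tonnes[i]
    v
  })
  out
}

solution_matrix <- function(solutions) {
  s <- do.call(rbind, lapply(solutions, function(x)
    x$summary[, c("cluster_id", "land_use", "area_ha", "fert", "irr_frac",
                  "mgmt")]))
  s <- s[order(s$cluster_id, s$land_use), ]
  as.matrix(s[, c("area_ha", "fert", "irr_frac", "mgmt")])
}

# Maximum relative change between two solution matrices; denominators are
# floored per variable so negligible quantities (a few hectares in a
# multi-Mha country) cannot dominate the convergence metric.
max_rel_change <- function(prev, new) {
  floors <- c(area_ha = 10, fert = 0.5, irr_frac = 5e-3, mgmt = 5e-3)
  m <- 0
  for (v in colnames(new)) {
    den <- pmax(abs(prev[, v]), abs(new[, v]), floors[[v]])
    m <- max(m, max(abs(new[, v] - prev[, v]) / den))
  }
  m
}

apply_solutions <- function(state, solutions) {
  world <- state$world
  tab <- state$clusters$table
  for (sol in solutions) {
    ta <- sol$target_areas
    for (j in unique(ta$cluster_id)) {
      cur <- tab[tab$cluster_id == j, ]
      deltas <- numeric(0)
      for (i in which(ta$cluster_id == j)) {
        u <- ta$land_use[i]
        cls <- if (u == "pasture") "cover_pasture" else paste0("cover_", u)
        cur_area <- cur[[sub("^cover_", "area_", cls)]]
        d <- ta$area_ha[i] - cur_area
        if (abs(d) > 1e-9) deltas[cls] <- d
      }
      if (!length(deltas)) next
      mem <- state$membership$cell_id[state$membership$cluster_id == j]
      idx <- match(mem, world$cells$cell_id)
      world$cells[idx, ] <- disaggregate(world$cells[idx, ], deltas,
                                         state$costs$min_natural_frac)
    }
  }
  state$world <- world
  state$clusters <- aggregate_clusters(
    world, state$membership, state$water,
    min_natural_frac = state$costs$min_natural_frac)
  state
}

#' Spin up the land-use system to a self-consistent base-year state
#'
#' Iterates the country optimisation under fixed base-year demand and net
#' imports (imposed as equalities), each round feeding the previous round's
#' land use back in as the existing land, until the maximum relative change
#' of any cluster area or intensity value falls below the threshold or the
#' iteration cap is reached.
#'
#' @param state an `agro_state` from [initialise_simulation()].
#' @param threshold convergence threshold on the maximum relative change
#'   (default 0.004 = 0.4%).
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   last state flagged.
#' @return the state with `spinup` holding `iterations`,
#'   `terminal_change`, `converged`, and `solutions` the final country
#'   solutions.
#' @export
spin_up <- function(state, threshold = NULL, max_iter = NULL) {
  stopifnot(inherits(state, "agro_state"))
  cfg <- state$config
  threshold <- threshold %||% cfg$spinup$threshold
  max_iter <- max_iter %||% cfg$spinup$max_iter
  world <- state$world
  demand <- country_base_demand(world)
  ni <- world$baseline_net_imports
  prev <- NULL
  change <- Inf
  iters <- 0
  repeat {
    iters <- iters + 1
    solutions <- lapply(sort(world$countries$country_id), function(cid) {
      niv <- setNames(ni$tonnes[ni$country_id == cid],
                      ni$commodity[ni$country_id == cid])
      optimise_country(subset_clusters(state$clusters, cid),
                       state$surfaces[[cid]], demand[[cid]],
                       state$market$prices, state$costs,
                       year = world$base_year, net_imports = niv,
                       china = cid %in% cfg$china_countries)
    })
    names(solutions) <- sort(world$countries$country_id)
    new <- solution_matrix(solutions)
    if (!is.null(prev)) {
      change <- max_rel_change(prev, new)
      if (change < threshold) break
    }
    if (iters >= max_iter) {
      if (is.null(prev) || change >= threshold)
        warning("spin-up did not converge in ", max_iter,
                " iterations (last change ", format(change, digits = 3), ")")
      break
    }
    prev <- new
    state <- apply_solutions(state, solutions)
  }
  state <- apply_solutions(state, solutions)
  state$solutions <- solutions
  state$spinup <- list(iterations = iters, terminal_change = change,
                       converged = is.finite(change) & change < threshold)
  if (isTRUE(cfg$market$prices_from_baseline %||% TRUE))
    state$market$prices <- baseline_prices(state, solutions)
  state
}

# Anchor initial world prices to the baseline solution's own marginal
# production costs (the cost of the last tonne supplied anywhere) so the
# free-running market starts inside the no-trade band it would otherwise
# spend years discovering; commodities without domestic production (e.g.
# energy crops before any deployment) keep their configured price.
baseline_prices <- function(state, solutions) {
  comms <- names(solutions[[1]]$marginal_cost)
  marg <- do.call(rbind, lapply(solutions, function(s)
    s$marginal_cost[comms]))
  colnames(marg) <- comms
  world_marg <- apply(marg, 2, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  prices <- state$market$prices
  for (cm in names(prices))
    if (!is.na(world_marg[cm] %||% NA)) prices[cm] <- world_marg[[cm]]
  cereal_m <- world_marg["cereals"] %||% NA
  feed_m <- world_marg["feed_eq"] %||% NA
  feed_mix <- suppressWarnings(max(cereal_m, feed_m, na.rm = TRUE))
  if (is.finite(feed_mix)) {
    if ("ruminant" %in% names(prices))
      prices["ruminant"] <- state$costs$fcr_ruminant * feed_mix
    if ("monogastric" %in% names(prices) && !is.na(cereal_m))
      prices["monogastric"] <- state$costs$fcr_monogastric * cereal_m
  }
  prices
}

#' Advance the coupled system by one year
#'
#' Order of operations: (1) yield anchors are the trailing mean over the
#' averaging window (constant anchors make this the identity); (2) demand is
#' projected from the year's income and population plus exogenous bioenergy;
#' (3) every country is optimised independently against the last settled
#' prices; (4) the world market settles, adjusting prices and stocks;
#' (5) cluster-level land-use changes are disaggregated to cells.
#'
#' @param state an `agro_state` after [spin_up()].
#' @param year calendar year to simulate.
#' @param anchor_series optional `function(year) -> anchor table` providing
#'   annual anchor sets; when supplied, surfaces are refitted to the
#'   trailing mean.
#' @return the updated state; `state$market$last_flows` holds the year's
#'   market record.
#' @export
run_timestep <- function(state, year, anchor_series = NULL) {
  stopifnot(inherits(state, "agro_state"))
  cfg <- state$config
  world <- state$world

  if (!is.null(anchor_series)) {
    win <- cfg$yield_avg_window
    sets <- lapply((year - win + 1):year, anchor_series)
    world$anchors <- average_anchor_sets(sets)
    state$world <- world
    state$clusters <- aggregate_clusters(
      world, state$membership, state$water,
      min_natural_frac = state$costs$min_natural_frac)
    sargs <- cfg$surfaces
    state$surfaces <- lapply(setNames(nm = world$countries$country_id),
      function(cid) cluster_surfaces(subset_clusters(state$clusters, cid),
                                     k_I = sargs$k_I, g0 = sargs$g0,
                                     k_M = sargs$k_M,
                                     tech_rate = sargs$tech_rate,
                                     base_year = world$base_year))
  }

  tr <- world$trajectories[world$trajectories$year == year, ]
  proj <- project_demand(state$model, year,
                         tr[, c("country_id", "gdp_pc")],
                         tr[, c("country_id", "population")],
                         convergence_on = isTRUE(cfg$demand$convergence_on))
  bio_year <- if (isTRUE(cfg$bioenergy_constant)) world$base_year else year
  bio <- bioenergy_demand(bio_year, world$baseline_firstgen)

  secondgen_local <- bio$secondgen_t * state$scale
  solutions <- lapply(sort(world$countries$country_id), function(cid) {
    d <- proj[proj$country_id == cid, ]
    v <- setNames(d$tonnes, d$commodity)
    fg <- bio$firstgen[bio$firstgen$country_id == cid, ]
    for (i in seq_len(nrow(fg)))
      v[fg$commodity[i]] <- v[fg$commodity[i]] + fg$tonnes[i]
    # export exposure cap: trade frictions keep any one year's exports to a
    # fraction of domestic demand (energy crops: of world demand)
    caps <- 0.3 * v
    if ("energy_crops" %in% names(state$market$prices))
      caps["energy_crops"] <- 0.6 * secondgen_local
    optimise_country(subset_clusters(state$clusters, cid),
                     state$surfaces[[cid]], v, state$market$prices,
                     state$costs, year = year,
                     china = cid %in% cfg$china_countries,
                     export_caps = caps)
  })
  names(solutions) <- sort(world$countries$country_id)

  state$market <- settle_market(state$market, solutions,
                                secondgen_demand_t = bio$secondgen_t *
                                  state$scale)
  state <- apply_solutions(state, solutions)
  validate_world(state$world)
  state$solutions <- solutions
  state$year <- year
  state
}

global_summary <- function(solutions, year) {
  s <- do.call(rbind, lapply(solutions, `[[`, "summary"))
  crop_uses <- setdiff(unique(s$land_use), "pasture")
  data.frame(
    year = year,
    cropland_Mha = sum(s$area_ha[s$land_use %in% crop_uses]) / 1e6,
    pasture_Mha = sum(s$area_ha[s$land_use == "pasture"]) / 1e6,
    nitrogen_Mt = sum(s$fert * s$area_ha) / 1e9,
    irrigation_km3 = sum(vapply(solutions, function(x)
      sum(x$water_used), 0)),
    objective_usd = sum(vapply(solutions, `[[`, 0, "objective"))
  )
}

#' Run a full scenario
#'
#' Generates (or takes) a world, initialises, spins up, then advances
#' annually from the base year to the configured end year, recording global
#' and per-country series, market trajectories and decadal cell maps.
#' Bit-identical under the same seed.
#'
#' @param config a `scenario_config`.
#' @param world optional pre-built `agro_world`; generated from
#'   `config$world` otherwise.
#' @param anchor_series optional annual anchor function (see
#'   [run_timestep()]).
#' @return object of class `agro_run` with elements `config`, `world`,
#'   `state`, `global`, `market`, `countries`, `maps`, `spinup`.
#' @export
run_scenario <- function(config = default_config(), world = NULL,
                         anchor_series = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$years$end < config$years$start)
    stop("years$end must be >= years$start", call. = FALSE)
  if (is.null(world))
    world <- generate_world(config$world$n_countries,
                            config$world$cells_per_country,
                            config$world$n_crops,
                            seed = sub_seed(config$seed, 1L))
  state <- initialise_simulation(world, config)
  state <- spin_up(state)

  years <- config$years$start:config$years$end
  global <- list(); mkt <- list(); ctry <- list(); maps <- list()
  record <- function(state, year) {
    g <- global_summary(state$solutions, year)
    if (!is.null(state$market$last_flows)) {
      f <- state$market$last_flows; f$year <- year
    } else {
      f <- data.frame(commodity = names(state$market$prices),
                      exports_t = 0, imports_t = 0, secondgen_t = 0,
                      oversupply_t = 0,
                      stock_t = as.numeric(state$market$stocks),
                      unmet_t = 0,
                      price = as.numeric(state$market$prices),
                      year = year)
    }
    co <- do.call(rbind, lapply(state$solutions, function(x)
      data.frame(year = year, country_id = x$country_id,
                 ag_area_Mha = sum(x$summary$area_ha) / 1e6,
                 objective_usd = x$objective,
                 imports_t = sum(x$trade$imports_t),
                 exports_t = sum(x$trade$exports_t))))
    list(g = g, f = f, co = co)
  }
  r <- record(state, years[1])
  global[[1]] <- r$g; mkt[[1]] <- r$f; ctry[[1]] <- r$co
  maps[[as.character(years[1])]] <- state$world$cells

  for (y in years[-1]) {
    state <- run_timestep(state, y, anchor_series)
    r <- record(state, y)
    global[[length(global) + 1]] <- r$g
    mkt[[length(mkt) + 1]] <- r$f
    ctry[[length(ctry) + 1]] <- r$co
    if ((y - years[1]) %% 10 == 0 || y == years[length(years)])
      maps[[as.character(y)]] <- state$world$cells
  }

  structure(list(config = config, world = world, state = state,
                 global = do.call(rbind, global),
                 market = do.call(rbind, mkt),
                 countries = do.call(rbind, ctry),
                 maps = maps, spinup = state$spinup),
            class = "agro_run")
}

#' @export
print.agro_run <- function(x, ...) {
  yr <- range(x$global$year)
  cat("Scenario run", yr[1], "-", yr[2], "\n")
  cat(sprintf("  cropland %.3f -> %.3f Mha; pasture %.3f -> %.3f Mha\n",
              x$global$cropland_Mha[1], tail(x$global$cropland_Mha, 1),
              x$global$pasture_Mha[1], tail(x$global$pasture_Mha, 1)))
  invisible(x)
}

#' Halton low-discrepancy sequence
#'
#' Quasi-random points in the unit hypercube used for parameter-uncertainty
#' sampling; deterministic, space-filling, and reproducible by construction.
#'
#' @param n number of points.
#' @param dim dimension (<= 13).
#' @param skip leading points to drop (burn-in).
#' @return an `n` by `dim` matrix in (0, 1).
#' @export
halton_sequence <- function(n, dim, skip = 20) {
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41)
  stopifnot(dim <= length(bases))
  radical_inverse <- function(i, b) {
    f <- 1; r <- 0
    while (i > 0) { f <- f / b; r <- r + f * (i %% b); i <- i %/% b }
    r
  }
  sapply(seq_len(dim), function(d)
    vapply(seq_len(n) + skip, radical_inverse, 0, b = bases[d]))
}

ensemble_parameters <- function() {
  c("crop_base_cost", "mgmt_cost_rate", "fert_price", "water_price_km3",
    "pasture_base_cost", "conv_cost_nat_ag", "conv_cost_crop_pasture",
    "tariff_rate", "transport_rate", "loss_rate")
}

#' Run a parameter-uncertainty ensemble
#'
#' Samples the cost and market parameters uniformly within
#' `central * (1 - h)` to `central * (1 + h)` at low-discrepancy (Halton)
#' points, runs the scenario once per member on a shared world, and
#' summarises per-year median and standard deviation of global cropland,
#' pasture, nitrogen and irrigation water.
#'
#' @param config a `scenario_config`.
#' @param n ensemble size (>= 1); defaults to `config$ensemble$n`.
#' @param half_width perturbation half-width `h` in \[0, 1\]; defaults to
#'   `config$ensemble$half_width`.
#' @return object of class `agro_ensemble`: `samples` (the parameter draws),
#'   `members` (per-member global series), `summary` (per-year median/sd).
#' @export
run_ensemble <- function(config = default_config(), n = NULL,
                         half_width = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  n <- n %||% config$ensemble$n
  half_width <- half_width %||% config$ensemble$half_width
  if (n < 1) stop("ensemble size must be >= 1", call. = FALSE)
  if (half_width < 0 || half_width > 1)
    stop("half_width must be in [0, 1]: parameters cannot go negative",
         call. = FALSE)
  pars <- ensemble_parameters()
  central <- unlist(default_costs()[pars])
  u <- halton_sequence(n, length(pars))
  samples <- t(central * (1 - half_width + 2 * half_width * t(u)))
  colnames(samples) <- pars

  world <- generate_world(config$world$n_countries,
                          config$world$cells_per_country,
                          config$world$n_crops,
                          seed = sub_seed(config$seed, 1L))
  members <- lapply(seq_len(n), function(i) {
    cfg_i <- config
    cfg_i$costs <- utils::modifyList(config$costs,
                                     as.list(samples[i, ]))
    run <- run_scenario(cfg_i, world = world)
    cbind(member = i, run$global)
  })
  all <- do.call(rbind, members)
  vars <- c("cropland_Mha", "pasture_Mha", "nitrogen_Mt", "irrigation_km3")
  summ <- do.call(rbind, lapply(split(all, all$year), function(d) {
    out <- data.frame(year = d$year[1])
    for (v in vars) {
      out[[paste0(v, "_median")]] <- median(d[[v]])
      out[[paste0(v, "_sd")]] <- sd(d[[v]])
    }
    out
  }))
  rownames(summ) <- NULL
  structure(list(samples = samples, members = all, summary = summ,
                 half_width = half_width, n = n),
            class = "agro_ensemble")
}

#' Average a list of anchor tables column-wise
#'
#' Computes the element-wise mean of the numeric anchor columns across a
#' trailing window of annual anchor sets (all sets must share the same
#' cell/crop rows in the same order).
#'
#' @param sets list of anchor tables.
#' @return a single anchor table of the same shape.
#' @export
average_anchor_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  out <- sets[[1]]
  num <- vapply(out, is.numeric, TRUE)
  if (length(sets) > 1) {
    for (s in sets[-1]) {
      stopifnot(identical(s$cell_id, out$cell_id),
                identical(s$crop, out$crop))
    }
    for (v in names(out)[num])
      out[[v]] <- Reduce(`+`, lapply(sets, `[[`, v)) / length(sets)
  }
  out
}
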