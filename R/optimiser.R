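#' Cluster-level yield surfaces including pasture
#'
#' Fits yield surfaces to a cluster set's area-weighted mean anchors and
#' appends a pasture response built from the cluster's mean pasture yield:
#' pasture responds weakly to fertiliser, moderately to irrigation, and to
#' management (reseeding, liming) like the crops.
#'
#' @param clusters an `agro_clusters`.
#' @param ... passed to [fit_yield_surface()] (calibration, shapes,
#'   tech_rate).
#' @return a `yield_surface` keyed by cluster id.
#' @export
cluster_surfaces <- function(clusters, ...) {
  an <- clusters$anchors
  tab <- clusters$table
  req <- tapply(an$irrig_req_km3_ha, an$cell_id, mean)
  py <- tab$pasture_yield
  pa <- data.frame(
    cell_id = tab$cluster_id, crop = "pasture",
    y_n0_rf = py, y_n200_rf = 1.30 * py, y_n1000_rf = 1.35 * py,
    y_n0_ir = 1.15 * py, y_n200_ir = 1.15 * 1.30 * py,
    y_n1000_ir = 1.15 * 1.35 * py,
    irrig_req_km3_ha = as.numeric(req[tab$cluster_id])
  )
  fit_yield_surface(rbind(an, pa), ...)
}

crop_commodity <- function(land_use) {
  ifelse(land_use == "pasture", "feed_eq",
         unname(AGROSIM_CROP_COMMODITY[land_use]))
}

default_fert_grid <- c(0, 50, 100, 200, 400, 700, 1000)
default_irr_grid <- c(0, 0.5, 1)
default_mgmt_grid <- c(0, 0.5, 1)

# Lower convex hull of per-hectare cost against yield; the efficient
# frontier of an intensity lattice (anything above the hull is dominated
# by a mixture of its neighbours).
lower_hull <- function(yield, cost) {
  o <- order(yield, cost)
  y <- yield[o]; cst <- cost[o]
  keep <- !duplicated(y)           # cheapest point at each yield
  y <- y[keep]; cst <- cst[keep]; o <- o[keep]
  h <- integer(0)
  for (i in seq_along(y)) {
    while (length(h) >= 2) {
      a <- h[length(h) - 1]; b <- h[length(h)]
      if ((cst[b] - cst[a]) * (y[i] - y[a]) >=
          (cst[i] - cst[a]) * (y[b] - y[a])) h <- h[-length(h)] else break
    }
    h <- c(h, i)
  }
  list(idx = o[h], yield = y[h], cost = cst[h])
}

# Build the supply-increment table for one country.  For every cluster x
# land use x land tier the intensity lattice is reduced to its efficient
# frontier and decomposed into a "base" option (occupy land at the
# cost-per-tonne-minimising intensity) plus "upgrade" increments that
# intensify already-occupied land along the frontier at increasing marginal
# cost per tonne and consume no additional land.  A merit-order sweep over
# these increments solves the land-or-intensity margin exactly for a single
# limiting resource.
build_options <- function(clusters, surfaces, costs, year,
                          fert_grid, irr_grid, mgmt_grid) {
  tab <- clusters$table
  uses <- unique(surfaces$crop)
  lat <- expand.grid(fert = fert_grid, irr_frac = irr_grid,
                     mgmt = mgmt_grid, land_use = uses,
                     cluster_id = tab$cluster_id,
                     stringsAsFactors = FALSE)
  i <- match(paste(lat$cluster_id, lat$land_use),
             paste(surfaces$cell_id, surfaces$crop))
  lat <- lat[!is.na(i), ]; i <- i[!is.na(i)]
  lat$yield <- evaluate_yield(surfaces, lat$cluster_id, lat$land_use,
                              lat$fert, lat$irr_frac, lat$mgmt, year)
  j <- match(lat$cluster_id, tab$cluster_id)
  lat$aridity <- tab$aridity[j]
  lat$irrig_req <- surfaces$irrig_req_km3_ha[i]
  lat$water_ha <- lat$irr_frac * lat$irrig_req / costs$irrigation_efficiency
  lat$cost_ha <- production_cost(1, lat$fert, lat$irr_frac, lat$mgmt,
                                 lat$irrig_req, lat$aridity, costs,
                                 pasture = lat$land_use == "pasture")
  lat <- lat[lat$yield > 1e-9, ]

  conv_for <- function(tn, pasture_use) {
    switch(tn,
           cropland = ifelse(pasture_use, costs$conv_cost_crop_pasture, 0),
           pasture = ifelse(pasture_use, 0, costs$conv_cost_crop_pasture),
           expansion = costs$conv_cost_nat_ag)
  }

  out <- vector("list", 512); no <- 0
  for (key in split(seq_len(nrow(lat)),
                    paste(lat$cluster_id, lat$land_use, sep = "\r"))) {
    sub <- lat[key, ]
    for (tn in c("cropland", "pasture", "expansion")) {
      conv <- conv_for(tn, sub$land_use[1] == "pasture")
      total <- sub$cost_ha + conv
      h <- lower_hull(sub$yield, total)
      avg <- h$cost / h$yield
      b <- which.min(avg)
      n_pts <- length(h$idx) - b + 1
      pts <- sub[h$idx[b:length(h$idx)], ]
      pts$point <- seq_len(n_pts)
      base <- pts[1, ]
      conv_b <- conv_for(tn, base$land_use == "pasture")
      rows <- data.frame(
        cluster_id = base$cluster_id, land_use = base$land_use, tier = tn,
        kind = "base", point = 1L, from_point = NA_integer_,
        fert = base$fert, irr_frac = base$irr_frac, mgmt = base$mgmt,
        yield = base$yield, dy = base$yield,
        cost_unit = base$cost_ha + conv_b,
        water_unit = base$water_ha, abs_water = base$water_ha,
        abs_cost = base$cost_ha + conv_b,
        cost_t = (base$cost_ha + conv_b) / base$yield)
      if (n_pts > 1) {
        up <- pts[-1, ]
        prev <- pts[-n_pts, ]
        rows <- rbind(rows, data.frame(
          cluster_id = up$cluster_id, land_use = up$land_use, tier = tn,
          kind = "upgrade", point = up$point, from_point = prev$point,
          fert = up$fert, irr_frac = up$irr_frac, mgmt = up$mgmt,
          yield = up$yield, dy = up$yield - prev$yield,
          cost_unit = up$cost_ha - prev$cost_ha,
          water_unit = up$water_ha - prev$water_ha,
          abs_water = up$water_ha, abs_cost = up$cost_ha + conv_b,
          cost_t = (up$cost_ha - prev$cost_ha) / (up$yield - prev$yield)))
      }
      no <- no + 1
      out[[no]] <- rows
    }
  }
  opts <- do.call(rbind, out[seq_len(no)])
  opts$commodity <- crop_commodity(opts$land_use)
  opts[order(opts$cost_t, opts$cluster_id, opts$land_use, opts$tier,
             opts$point), ]
}

country_pools <- function(clusters, crops, costs, china = FALSE) {
  tab <- clusters$table
  crop_cols <- paste0("area_", crops)
  crop_cols <- intersect(crop_cols, names(tab))
  pool_crop <- rowSums(tab[, crop_cols, drop = FALSE])
  pool_exp <- tab$avail_natural_ha
  if (china)
    pool_exp <- pmin(pool_exp, 2 * costs$china_deforestation_cap *
                       tab$forest_ha)
  list(cropland = setNames(pool_crop, tab$cluster_id),
       pasture = setNames(tab$area_pasture, tab$cluster_id),
       expansion = setNames(pool_exp, tab$cluster_id),
       water = setNames(tab$water_km3, tab$cluster_id))
}

#' Least-cost land use, livestock and trade for one country
#'
#' Chooses cluster-level areas and input intensities (fertiliser,
#' irrigation, management) for every land-use type, livestock feed versus
#' pasture, and imports/exports, minimising total cost subject to commodity
#' balance, water availability, protected areas, the minimum natural
#' fraction and (optionally) a national deforestation cap.  The solver is a
#' deterministic merit-order allocation: all activities are discretised on
#' an intensity lattice across three land tiers (existing cropland, existing
#' pasture, expansion into convertible natural land, each with its
#' conversion cost) and demand is filled in ascending order of marginal cost
#' per tonne, with import options competing at the inflated world price;
#' production for export continues while marginal cost stays below the world
#' price.
#'
#' @param clusters an `agro_clusters` for a single country.
#' @param surfaces cluster-level `yield_surface` from [cluster_surfaces()].
#' @param demand named vector of commodity demand (t/yr): food plus
#'   first-generation bioenergy, over the country's food commodities.
#' @param prices named vector of world prices ($/t) covering the demand
#'   commodities and, if energy crops are modelled, `energy_crops`.
#' @param costs a `cost_parameters` list.
#' @param year calendar year for yield evaluation (default: surface base
#'   year).
#' @param net_imports named vector fixing net imports per commodity
#'   (spin-up mode); `NULL` for price-driven trade.
#' @param china logical: apply the national deforestation cap.
#' @param export_margin exports require marginal cost below
#'   `price * (1 - export_margin)`.
#' @param export_caps optional named vector of per-commodity export limits
#'   (t/yr) representing trade frictions and handling capacity; `NULL`
#'   leaves exports bounded only by land and water.
#' @param fert_grid,irr_grid,mgmt_grid intensity lattice.
#' @return object of class `country_solution`; see Details.
#' @details The solution contains `activities` (every allocated lattice
#'   activity), `summary` (one row per cluster and land-use type with area
#'   and production-weighted mean intensities — the four decision variables
#'   per land-use type), `trade`, `production`, `feed`, `objective` ($/yr),
#'   `water_used`, and `target_areas` (per cluster and cover class, ha) for
#'   disaggregation.
#' @export
optimise_country <- function(clusters, surfaces, demand, prices, costs,
                             year = NULL, net_imports = NULL, china = FALSE,
                             export_margin = 0.02, export_caps = NULL,
                             fert_grid = default_fert_grid,
                             irr_grid = default_irr_grid,
                             mgmt_grid = default_mgmt_grid) {
  stopifnot(inherits(clusters, "agro_clusters"),
            inherits(surfaces, "yield_surface"),
            inherits(costs, "cost_parameters"))
  if (any(!is.finite(demand)) || any(demand < 0))
    stop("demand must be finite and non-negative", call. = FALSE)
  country_id <- clusters$table$country_id[1]
  if (is.null(year)) year <- attr(surfaces, "base_year")
  crops <- setdiff(unique(surfaces$crop), "pasture")
  food_comms <- intersect(names(demand), AGROSIM_FOOD_COMMODITIES)
  crop_comms <- setdiff(food_comms, c("ruminant", "monogastric"))
  import_infl <- 1 + costs$tariff_rate + costs$transport_rate +
    costs$loss_rate

  opts <- build_options(clusters, surfaces, costs, year,
                        fert_grid, irr_grid, mgmt_grid)
  pools <- country_pools(clusters, crops, costs, china)
  free_trade <- is.null(net_imports)

  # --- production targets and fixed trade --------------------------------
  imports <- setNames(numeric(length(food_comms)), food_comms)
  exports <- imports
  target <- imports
  for (cm in food_comms) {
    ni <- if (free_trade) 0 else (net_imports[cm] %||% 0)
    if (is.na(ni)) ni <- 0
    target[cm] <- max(0, demand[cm] - ni)
    if (!free_trade) {
      imports[cm] <- max(ni, 0)
      exports[cm] <- max(-ni, 0)
      target[cm] <- max(0, demand[cm] - ni)  # production covers demand - NI
      # a required export is extra production
      target[cm] <- target[cm] + 0           # demand - ni already includes it
    }
  }

  # --- livestock: import-or-produce, then feed requirements --------------
  min_cost <- function(cm) {
    sel <- opts$commodity == cm
    if (!any(sel)) Inf else min(opts$cost_t[sel])
  }
  cereal_min <- min_cost("cereals")
  pasture_min <- min_cost("feed_eq")
  R <- target["ruminant"] %||% 0; if (is.na(R)) R <- 0
  M <- target["monogastric"] %||% 0; if (is.na(M)) M <- 0
  if (free_trade) {
    if ("monogastric" %in% food_comms) {
      imp_p <- prices["monogastric"] * import_infl
      dom_est <- costs$fcr_monogastric * cereal_min
      if (is.finite(imp_p) && imp_p < dom_est) {
        imports["monogastric"] <- M; M <- 0
      }
    }
    if ("ruminant" %in% food_comms) {
      imp_p <- prices["ruminant"] * import_infl
      dom_est <- costs$fcr_ruminant * min(cereal_min, pasture_min)
      if (is.finite(imp_p) && imp_p < dom_est) {
        imports["ruminant"] <- R; R <- 0
      }
    }
  }
  lsb <- livestock_balance(R, M, pasture_output = 0,
                           fcr_ruminant = costs$fcr_ruminant,
                           fcr_monogastric = costs$fcr_monogastric)

  D <- setNames(numeric(length(crop_comms) + 1),
                c(crop_comms, "feed_eq"))
  for (cm in crop_comms) D[cm] <- target[cm]
  if ("cereals" %in% names(D))
    D["cereals"] <- D["cereals"] + lsb$feed_monogastric
  D["feed_eq"] <- lsb$requirement_ruminant

  # --- merit-order allocation -------------------------------------------
  # Import prices cap the domestic marginal cost worth paying per commodity.
  imp_price <- setNames(rep(Inf, length(D)), names(D))
  if (free_trade) {
    for (cm in names(D)) {
      src <- if (cm == "feed_eq") "cereals" else cm
      p <- prices[src] %||% NA_real_
      if (!is.na(p)) imp_price[cm] <- p * import_infl
    }
  }
  cm_opt <- opts$commodity
  is_pasture_row <- opts$land_use == "pasture"
  pool_key <- paste(opts$cluster_id, opts$land_use, opts$tier, sep = "\r")
  ledger_key <- paste(pool_key, opts$point, sep = "\r")
  from_key <- ifelse(opts$kind == "upgrade",
                     paste(pool_key, opts$from_point, sep = "\r"), NA)

  # One merit-order sweep over the supply increments.  Base increments
  # occupy land; upgrade increments intensify already-occupied land of the
  # same pool at increasing marginal cost and use no extra land.
  # Cross-class land conversion (cropland used for pasture or vice versa)
  # is capped per cluster at `cross_cap`: converting land the other class
  # still needs would force it to rebuild on natural land at a higher
  # combined cost, so only genuinely surplus land may switch class.
  run_alloc <- function(Dleft, cross_cap_crop, cross_cap_past,
                        do_exports) {
    obj <- 0
    p_crop <- pools$cropland; p_past <- pools$pasture
    p_exp <- pools$expansion; p_wat <- pools$water
    ex_cap <- export_cap_left
    ledger <- new.env(parent = emptyenv())   # area per (pool, hull point)
    led_get <- function(k) if (is.null(ledger[[k]])) 0 else ledger[[k]]
    exports_extra <- setNames(numeric(length(prices)), names(prices))
    pasture_feed <- 0; crop_feed <- 0
    marg_cost <- setNames(rep(NA_real_, length(Dleft)), names(Dleft))
    for (pass in c("demand", if (do_exports) "export")) {
      max_price <- if (free_trade && length(prices))
        max(prices, na.rm = TRUE) else 0
      for (r in seq_len(nrow(opts))) {
        if (pass == "demand" && all(Dleft <= 1e-9)) break
        if (pass == "export" && opts$cost_t[r] >= max_price) break
        if (pass == "demand") {
          serves <- if (cm_opt[r] == "cereals") c("cereals", "feed_eq")
                    else cm_opt[r]
          serves <- serves[serves %in% names(Dleft)]
        } else {
          cm <- cm_opt[r]
          if (cm == "feed_eq") next
          p <- prices[cm] %||% NA_real_
          if (is.na(p) || opts$cost_t[r] >= p * (1 - export_margin)) next
          serves <- paste0("export_", cm)
        }
        for (cm in serves) {
          rem <- if (pass == "demand") Dleft[cm]
                 else (ex_cap[sub("^export_", "", cm)] %||% Inf)
          if (is.na(rem)) rem <- Inf
          if (rem <= 1e-9) next
          if (pass == "demand" && opts$cost_t[r] >= imp_price[cm]) next
          j <- opts$cluster_id[r]; tn <- opts$tier[r]
          if (opts$kind[r] == "base") {
            cap <- switch(tn, cropland = p_crop[j], pasture = p_past[j],
                          expansion = p_exp[j])
            if (tn == "cropland" && is_pasture_row[r])
              cap <- min(cap, cross_cap_crop[j])
            if (tn == "pasture" && !is_pasture_row[r])
              cap <- min(cap, cross_cap_past[j])
          } else {
            cap <- led_get(from_key[r])      # upgrade: land already occupied
          }
          if (cap <= 1e-9) next
          area <- min(rem / opts$dy[r], cap)
          if (opts$water_unit[r] > 0)
            area <- min(area, p_wat[j] / opts$water_unit[r])
          if (area <= 1e-9) next
          q <- area * opts$dy[r]
          if (opts$kind[r] == "base") {
            if (tn == "cropland") {
              p_crop[j] <- p_crop[j] - area
              if (is_pasture_row[r])
                cross_cap_crop[j] <- cross_cap_crop[j] - area
            } else if (tn == "pasture") {
              p_past[j] <- p_past[j] - area
              if (!is_pasture_row[r])
                cross_cap_past[j] <- cross_cap_past[j] - area
            } else p_exp[j] <- p_exp[j] - area
          } else {
            ledger[[from_key[r]]] <- led_get(from_key[r]) - area
          }
          ledger[[ledger_key[r]]] <- led_get(ledger_key[r]) + area
          p_wat[j] <- p_wat[j] - area * opts$water_unit[r]
          obj <- obj + area * opts$cost_unit[r]
          if (pass == "demand") {
            Dleft[cm] <- Dleft[cm] - q
            marg_cost[cm] <- max(marg_cost[cm], opts$cost_t[r], na.rm = TRUE)
            if (cm == "feed_eq") {
              if (is_pasture_row[r]) pasture_feed <- pasture_feed + q
              else crop_feed <- crop_feed + q
            }
          } else {
            src <- sub("^export_", "", cm)
            ex_cap[src] <- ex_cap[src] - q
            exports_extra[src] <- exports_extra[src] + q
          }
        }
      }
    }
    # materialise the final area ledger as activity rows
    keys <- ls(ledger)
    keep <- keys[vapply(keys, function(k) ledger[[k]] > 1e-9, TRUE)]
    i <- match(keep, ledger_key)
    alloc <- if (length(keep)) data.frame(
      cluster_id = opts$cluster_id[i], land_use = opts$land_use[i],
      tier = opts$tier[i], fert = opts$fert[i],
      irr_frac = opts$irr_frac[i], mgmt = opts$mgmt[i],
      area_ha = vapply(keep, function(k) ledger[[k]], 0),
      yield_t_ha = opts$yield[i],
      water_km3 = vapply(keep, function(k) ledger[[k]], 0) *
        opts$abs_water[i],
      cost_usd = vapply(keep, function(k) ledger[[k]], 0) *
        opts$abs_cost[i]
    ) else data.frame(
      cluster_id = character(), land_use = character(), tier = character(),
      fert = numeric(), irr_frac = numeric(), mgmt = numeric(),
      area_ha = numeric(), yield_t_ha = numeric(), water_km3 = numeric(),
      cost_usd = numeric())
    if (nrow(alloc)) {
      alloc$production_t <- alloc$area_ha * alloc$yield_t_ha
      alloc <- alloc[order(alloc$cluster_id, alloc$land_use, alloc$tier,
                           alloc$fert, alloc$irr_frac, alloc$mgmt), ]
      rownames(alloc) <- NULL
    } else {
      alloc$production_t <- numeric(0)
    }
    list(alloc = alloc, D = Dleft, obj = obj,
         exports_extra = exports_extra, pasture_feed = pasture_feed,
         crop_feed = crop_feed, marginal_cost = marg_cost)
  }

  export_cap_left <- export_caps %||%
    setNames(rep(Inf, length(prices)), names(prices))
  zero_cap <- setNames(rep(0, nrow(clusters$table)),
                       clusters$table$cluster_id)

  # pass 1: no cross-class conversion, demand only -> own-class land needs
  p1 <- run_alloc(D, zero_cap, zero_cap, do_exports = FALSE)
  used <- function(a, from_tier, pasture_rows) {
    sel <- a$tier == from_tier &
      (if (pasture_rows) a$land_use == "pasture" else a$land_use != "pasture")
    out <- zero_cap
    if (any(sel)) {
      s <- tapply(a$area_ha[sel], a$cluster_id[sel], sum)
      out[names(s)] <- s
    }
    out
  }
  own_crop_used <- used(p1$alloc, "cropland", pasture_rows = FALSE)
  own_past_used <- used(p1$alloc, "pasture", pasture_rows = TRUE)
  surplus_crop <- pmax(pools$cropland - own_crop_used, 0)
  surplus_past <- pmax(pools$pasture - own_past_used, 0)

  # pass 2 (final): cross-class conversion capped at the surplus;
  # price-driven exports only when trade is free
  p2 <- run_alloc(D, surplus_crop, surplus_past, do_exports = free_trade)
  alloc <- p2$alloc
  D <- p2$D
  obj_cost <- p2$obj
  import_extra <- setNames(numeric(length(D)), names(D))

  # unmet demand: import (free trade) or infeasible (fixed trade)
  for (cm in names(D)) {
    if (D[cm] <= 1e-6) { D[cm] <- 0; next }
    if (!free_trade)
      stop("infeasible: cannot meet ", cm, " production target for ",
           country_id, " (", format(D[cm], digits = 4),
           " t short; land or water binding)", call. = FALSE)
    src <- if (cm == "feed_eq") "cereals" else cm
    import_extra[cm] <- D[cm]
    imports[src] <- (imports[src] %||% 0) + D[cm]
    obj_cost <- obj_cost + D[cm] * imp_price[cm]
    D[cm] <- 0
  }

  # --- accounting --------------------------------------------------------
  exp_q <- p2$exports_extra[p2$exports_extra > 0]
  for (cm in names(exp_q)) {
    prev <- exports[cm]
    exports[cm] <- (if (is.na(prev)) 0 else prev) + exp_q[[cm]]
  }
  export_rev <- sum(exports * prices[names(exports)], na.rm = TRUE)

  prod_by_cm <- tapply(alloc$production_t,
                       crop_commodity(alloc$land_use), sum)
  production <- setNames(numeric(0), character(0))
  for (cm in names(prod_by_cm)) production[cm] <- prod_by_cm[[cm]]
  production["ruminant"] <- R
  production["monogastric"] <- M

  pasture_used <- p2$pasture_feed
  feed_r_dom <- p2$crop_feed
  feed <- data.frame(
    livestock = c("ruminant", "monogastric"),
    pasture_t = c(pasture_used, 0),
    feed_t = unname(c(feed_r_dom + import_extra[["feed_eq"]],
                      lsb$feed_monogastric)))

  # per cluster x land use summary: the four decision variables
  uses <- c(crops, "pasture")
  summ <- expand.grid(cluster_id = clusters$table$cluster_id,
                      land_use = uses, stringsAsFactors = FALSE)
  key <- paste(alloc$cluster_id, alloc$land_use)
  agg <- function(v, w) {
    x <- tapply(v * w, key, sum); a <- tapply(w, key, sum)
    out <- x / pmax(a, 1e-300); out[a == 0] <- 0; out
  }
  a_tot <- tapply(alloc$area_ha, key, sum)
  skey <- paste(summ$cluster_id, summ$land_use)
  summ$area_ha <- as.numeric(a_tot[skey]); summ$area_ha[is.na(summ$area_ha)] <- 0
  for (v in c("fert", "irr_frac", "mgmt")) {
    m <- agg(alloc[[v]], alloc$area_ha)
    summ[[v]] <- as.numeric(m[skey]); summ[[v]][is.na(summ[[v]])] <- 0
  }
  p_tot <- tapply(alloc$production_t, key, sum)
  summ$production_t <- as.numeric(p_tot[skey])
  summ$production_t[is.na(summ$production_t)] <- 0

  target_areas <- summ[, c("cluster_id", "land_use", "area_ha")]
  water_used <- tapply(alloc$water_km3, alloc$cluster_id, sum)

  trade <- data.frame(commodity = union(names(imports), names(exports)))
  trade$imports_t <- as.numeric(imports[trade$commodity])
  trade$exports_t <- as.numeric(exports[trade$commodity])
  trade$imports_t[is.na(trade$imports_t)] <- 0
  trade$exports_t[is.na(trade$exports_t)] <- 0
  # no simultaneous import and export of the same commodity
  net <- trade$imports_t - trade$exports_t
  trade$imports_t <- pmax(net, 0)
  trade$exports_t <- pmax(-net, 0)

  structure(list(
    country_id = country_id, year = year, activities = alloc,
    summary = summ, trade = trade, production = production, feed = feed,
    objective = obj_cost - export_rev, water_used = water_used,
    target_areas = target_areas, demand = demand,
    marginal_cost = p2$marginal_cost,
    free_trade = free_trade, china = china
  ), class = "country_solution")
}

#' @export
print.country_solution <- function(x, ...) {
  cat("Country solution:", x$country_id, "year", x$year, "\n")
  cat("  objective:", format(x$objective, big.mark = ","), "$/yr\n")
  cat("  agricultural area:", format(sum(x$summary$area_ha) / 1e6,
                                     digits = 4), "Mha\n")
  tr <- x$trade[x$trade$imports_t > 0 | x$trade$exports_t > 0, ]
  if (nrow(tr)) { cat("  trade (t/yr):\n"); print(tr, row.names = FALSE) }
  invisible(x)
}

#' Verify the feasibility of a country solution
#'
#' Audits the six feasibility classes: commodity balance, water limits,
#' protected areas, minimum natural fraction, equal debit of forest and
#' other natural land on expansion (enforced at disaggregation), and the
#' national deforestation cap.  Violations raise errors; a clean pass
#' returns invisibly.
#'
#' @param solution a `country_solution`.
#' @param clusters the `agro_clusters` it was solved on.
#' @param costs the `cost_parameters` used.
#' @param tol numeric tolerance on balances.
#' @return `TRUE` invisibly if all checks pass.
#' @export
validate_solution <- function(solution, clusters, costs, tol = 1e-6) {
  tab <- clusters$table
  demand <- solution$demand
  # (i) commodity balance: production + imports - exports - feed >= demand
  tr <- solution$trade
  for (cm in names(demand)) {
    prod <- solution$production[cm] %||% 0
    if (is.na(prod)) prod <- 0
    i <- tr$imports_t[match(cm, tr$commodity)] %||% 0
    e <- tr$exports_t[match(cm, tr$commodity)] %||% 0
    if (is.na(i)) i <- 0
    if (is.na(e)) e <- 0
    # all feed (domestic and imported, both livestock types) is cereals
    feed_use <- if (cm == "cereals") sum(solution$feed$feed_t) else 0
    bal <- prod + i - e - feed_use - demand[cm]
    if (bal < -tol * max(1, demand[cm]))
      stop("commodity balance violated for ", cm, ": ", bal, call. = FALSE)
    if (i > tol && e > tol)
      stop("simultaneous import and export of ", cm, call. = FALSE)
  }
  # (ii) water
  wu <- solution$water_used
  for (j in names(wu)) {
    cap <- tab$water_km3[match(j, tab$cluster_id)]
    if (wu[[j]] > cap + tol)
      stop("water constraint violated in cluster ", j, call. = FALSE)
  }
  # (iii)+(iv) protection and minimum natural: expansion within the
  # convertible pool
  agg <- tapply(solution$activities$area_ha[
    solution$activities$tier == "expansion"],
    solution$activities$cluster_id[solution$activities$tier == "expansion"],
    sum)
  for (j in names(agg)) {
    cap <- tab$avail_natural_ha[match(j, tab$cluster_id)]
    if (agg[[j]] > cap + tol)
      stop("expansion exceeds convertible natural land in ", j,
           call. = FALSE)
    # (vi) deforestation cap: half of expansion is debited from forest
    if (isTRUE(solution$china)) {
      fcap <- 2 * costs$china_deforestation_cap *
        tab$forest_ha[match(j, tab$cluster_id)]
      if (agg[[j]] > fcap + tol)
        stop("deforestation cap violated in ", j, call. = FALSE)
    }
  }
  # areas non-negative, intensities in range
  s <- solution$summary
  if (any(s$area_ha < -tol) || any(s$irr_frac < -tol | s$irr_frac > 1 + tol) ||
      any(s$mgmt < -tol | s$mgmt > 1 + tol) || any(s$fert < -tol))
    stop("decision variable out of range", call. = FALSE)
  invisible(TRUE)
}
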