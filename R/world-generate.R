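#' Global demand-curve parameters used by the synthetic world
#'
#' The generator draws per-capita consumption from a log-log income
#' relationship per commodity group; these are the "true" coefficients it
#' uses, exposed so recovery tests can compare fitted against generating
#' values.  Slopes are positive for income-elastic groups (livestock, oil
#' crops) and negative for staples whose consumption declines with income
#' (pulses, starchy roots).
#'
#' @return data.frame with columns `commodity`, `a` (intercept of
#'   `ln(consumption per capita)` in t/person/yr), `b` (slope on
#'   `ln(GDP per capita)` in 2010 US$).
#' @export
demand_truth <- function() {
  data.frame(
    commodity = AGROSIM_FOOD_COMMODITIES,
    a = c(-2.75, -5.81, -2.53, -1.89, -7.13, -7.65),
    b = c(0.10, 0.25, -0.15, -0.10, 0.35, 0.45)
  )
}

# Smooth a standard-normal draw over cell coordinates with a Gaussian kernel
# so neighbouring cells within a country are positively correlated.
smooth_field <- function(lat, lon, length_deg = 1.0) {
  n <- length(lat)
  z <- rnorm(n)
  if (n == 1) return(z)
  d2 <- outer(lat, lat, "-")^2 + outer(lon, lon, "-")^2
  w <- exp(-d2 / (2 * length_deg^2))
  w <- w / rowSums(w)
  f <- as.vector(w %*% z)
  s <- sd(f)
  if (s > 0) f / s else f
}

#' Generate a synthetic world
#'
#' Builds a miniature gridded world: rectangular country blocks on the
#' half-degree lattice, spatially autocorrelated yield anchors at the six
#' factorial fertiliser-by-water combinations, runoff, land-cover fractions
#' that close to one, protection masks, food-production units (FPUs) for
#' water pooling, and national socio-economic trajectories whose
#' income-consumption structure matches the log-log demand model.  The
#' output emulates the statistical shape of gridded vegetation-model yield
#' potentials plus national statistics tables; it makes no attempt to mimic
#' real geography.
#'
#' @param n_countries number of countries (>= 1).
#' @param cells_per_country grid cells per country (>= 1).
#' @param n_crops number of crop types, 1..7; the first `n_crops` of the
#'   canonical set (C3 cereals, C4 cereals, rice, oil crops, pulses, starchy
#'   roots, energy crops) are used.
#' @param seed integer seed; output is reproducible given the seed.
#' @param resolution_deg angular cell size (degrees).
#' @return an object of class `agro_world`: a list with elements `cells`,
#'   `anchors`, `countries`, `trajectories`, `baseline_consumption`,
#'   `baseline_net_imports`, `fpus`, `demand_offsets`, `crops`,
#'   `resolution_deg`, `base_year`.
#' @examples
#' w <- generate_world(2, 9, n_crops = 2, seed = 1)
#' nrow(w$cells)
#' @export
generate_world <- function(n_countries, cells_per_country, n_crops = 7,
                           seed = 1, resolution_deg = 0.5) {
  if (!is.numeric(n_countries) || n_countries < 1 ||
      !is.numeric(cells_per_country) || cells_per_country < 1 ||
      !is.numeric(n_crops) || n_crops < 1 || n_crops > length(AGROSIM_CROPS))
    stop("n_countries, cells_per_country >= 1 and 1 <= n_crops <= ",
         length(AGROSIM_CROPS), call. = FALSE)
  n_countries <- as.integer(n_countries)
  cells_per_country <- as.integer(cells_per_country)
  crops <- AGROSIM_CROPS[seq_len(n_crops)]
  commodities <- intersect(
    AGROSIM_FOOD_COMMODITIES,
    c(unique(unname(AGROSIM_CROP_COMMODITY[crops])), "ruminant",
      "monogastric"))
  set.seed(as.integer(seed))

  res <- resolution_deg
  ncol_block <- max(1L, ceiling(sqrt(cells_per_country)))
  nrow_block <- ceiling(cells_per_country / ncol_block)

  cells_list <- vector("list", n_countries)
  anchors_list <- vector("list", n_countries)
  offsets_list <- vector("list", n_countries)
  country_rows <- vector("list", n_countries)

  # country blocks side by side along longitude, mid-latitude band
  lat0_idx <- lattice_index(45, res, -90)

  for (ci in seq_len(n_countries)) {
    cid <- sprintf("C%02d", ci)
    idx <- seq_len(cells_per_country) - 1L
    row_i <- idx %/% ncol_block
    col_i <- idx %% ncol_block
    lon_idx <- (ci - 1L) * (ncol_block + 2L) + col_i
    lat <- lattice_centre(lat0_idx + row_i, res, -90)
    lon <- lattice_centre(lon_idx, res, -180)
    area <- cell_area_ha(lat, res)

    fert  <- smooth_field(lat, lon)        # soil fertility driver
    arid_f <- smooth_field(lat, lon)
    past_f <- smooth_field(lat, lon)
    crop_share_f <- smooth_field(lat, lon)
    aridity <- stats::plogis(0.9 * arid_f)

    # factorial yield anchors, monotone by construction
    y0 <- pmax(0.3, 1.6 + 0.8 * fert)
    gain200 <- pmax(0.3, 3.0 + 1.0 * smooth_field(lat, lon))
    # diminishing returns: most of the response is realised by 200 kgN/ha
    gain1000 <- pmin(pmax(0.1, 0.8 + 0.3 * smooth_field(lat, lon)),
                     0.9 * gain200)
    irr_gain <- 1 + 0.8 * aridity          # arid cells respond more to water
    crop_mult <- exp(seq(0.15, -0.15, length.out = length(crops)) +
                       0.05 * seq_along(crops))
    an <- do.call(rbind, lapply(seq_along(crops), function(k) {
      m <- crop_mult[k] * exp(0.10 * smooth_field(lat, lon))
      y_n0 <- y0 * m
      y_n200 <- (y0 + gain200) * m
      y_n1000 <- (y0 + gain200 + gain1000) * m
      data.frame(
        cell_id = paste0(cid, "_", seq_len(cells_per_country)),
        crop = crops[k],
        y_n0_rf = y_n0, y_n200_rf = y_n200, y_n1000_rf = y_n1000,
        y_n0_ir = y_n0 * irr_gain, y_n200_ir = y_n200 * irr_gain,
        y_n1000_ir = y_n1000 * irr_gain,
        # full-requirement irrigation volume, km^3 per ha per yr
        irrig_req_km3_ha = (2000 + 6000 * aridity) * 1e-9
      )
    }))

    pasture_yield <- pmax(0.5, 3.0 + 1.2 * past_f)
    runoff_depth_m <- pmax(0.02, 0.25 + 0.12 * smooth_field(lat, lon))
    runoff_km3 <- runoff_depth_m * area * 1e4 * 1e-9

    # baseline land cover: cropland split over crops by yield, closure to 1
    crop_frac <- 0.10 + 0.10 * stats::plogis(crop_share_f)
    pasture_frac <- 0.08 + 0.10 * stats::plogis(past_f)
    urban_frac <- 0.02 + 0.02 * runif(cells_per_country)
    nat_frac <- pmax(0.05, 1 - crop_frac - pasture_frac - urban_frac)
    tot <- crop_frac + pasture_frac + urban_frac + nat_frac
    crop_frac <- crop_frac / tot; pasture_frac <- pasture_frac / tot
    urban_frac <- urban_frac / tot; nat_frac <- nat_frac / tot

    food_crops <- setdiff(crops, "energy_crops")
    if (length(food_crops) == 0) food_crops <- crops
    wts <- vapply(food_crops, function(cr)
      an$y_n200_rf[an$crop == cr], numeric(cells_per_country))
    wts <- matrix(wts, nrow = cells_per_country)
    wts <- wts / rowSums(wts)
    cover_crops <- matrix(0, cells_per_country, length(crops),
                          dimnames = list(NULL, crops))
    cover_crops[, food_crops] <- wts * crop_frac
    forest_frac <- nat_frac * (0.5 + 0.15 * tanh(smooth_field(lat, lon)))
    other_nat <- nat_frac - forest_frac
    protected <- runif(cells_per_country, 0, 0.4) * (forest_frac + other_nat)

    cell_df <- data.frame(
      cell_id = paste0(cid, "_", seq_len(cells_per_country)),
      lat = lat, lon = lon, area_ha = area,
      country_id = cid,
      fpu_id = paste0("F", ci, "_", ifelse(col_i < ncol_block / 2, "w", "e")),
      protected_frac = protected, aridity = aridity,
      runoff_km3 = runoff_km3, pasture_yield = pasture_yield
    )
    for (cr in crops) cell_df[[paste0("cover_", cr)]] <- cover_crops[, cr]
    cell_df$cover_pasture <- pasture_frac
    cell_df$cover_forest <- forest_frac
    cell_df$cover_natural <- other_nat
    cell_df$cover_urban <- urban_frac

    cells_list[[ci]] <- cell_df
    anchors_list[[ci]] <- an

    # socio-economics sized so baseline demand is feasible on ~15% cropland
    gdp0 <- exp(runif(1, log(2000), log(40000)))
    mean_y <- mean(an$y_n200_rf)
    country_area <- sum(area)
    tr <- demand_truth()
    d0 <- rnorm(nrow(tr), 0, 0.15)
    pc <- setNames(exp(tr$a + tr$b * log(gdp0) + d0), tr$commodity)
    # cropland-equivalent per-capita demand: food crops plus monogastric
    # feed and the feed share of ruminant nutrition not met from pasture
    percap_equiv <- sum(pc[c("cereals", "oil_crops", "pulses",
                             "starchy_roots")]) +
      4 * pc[["monogastric"]] + 0.5 * 7 * pc[["ruminant"]]
    pop0 <- 0.12 * country_area * mean_y / max(percap_equiv, 1e-6)
    pop0 <- round(pop0)
    country_rows[[ci]] <- data.frame(
      country_id = cid, gdp_pc_2010 = gdp0, population_2010 = pop0,
      gdp_growth = runif(1, 0.01, 0.035), pop_growth = runif(1, 0.0, 0.012)
    )
    offsets_list[[ci]] <- data.frame(country_id = cid,
                                     commodity = tr$commodity, d0 = d0)
  }

  cells <- do.call(rbind, cells_list)
  anchors <- do.call(rbind, anchors_list)
  countries <- do.call(rbind, country_rows)
  offsets <- do.call(rbind, offsets_list)
  rownames(cells) <- rownames(anchors) <- rownames(countries) <-
    rownames(offsets) <- NULL

  # future trajectories 2010..2100
  years <- AGROSIM_BASE_YEAR:2100L
  trajectories <- do.call(rbind, lapply(seq_len(n_countries), function(ci) {
    co <- countries[ci, ]
    data.frame(
      country_id = co$country_id, year = years,
      gdp_pc = co$gdp_pc_2010 * (1 + co$gdp_growth)^(years - AGROSIM_BASE_YEAR),
      population = co$population_2010 *
        (1 + co$pop_growth)^(years - AGROSIM_BASE_YEAR)
    )
  }))

  offsets <- offsets[offsets$commodity %in% commodities, ]
  rownames(offsets) <- NULL
  tr <- demand_truth()
  base_cons <- merge(offsets, tr, by = "commodity")
  base_cons <- merge(base_cons, countries[, c("country_id", "gdp_pc_2010",
                                              "population_2010")],
                     by = "country_id")
  base_cons$tonnes <- exp(base_cons$a + base_cons$b * log(base_cons$gdp_pc_2010) +
                            base_cons$d0) * base_cons$population_2010
  baseline_consumption <- base_cons[order(base_cons$country_id,
                                          base_cons$commodity),
                                    c("country_id", "commodity", "tonnes")]
  rownames(baseline_consumption) <- NULL

  # net imports: +-10% of consumption, centred so world trade balances
  ni <- baseline_consumption
  ni$tonnes <- ni$tonnes * runif(nrow(ni), -0.1, 0.1)
  ni_mean <- stats::ave(ni$tonnes, ni$commodity)
  ni$tonnes <- ni$tonnes - ni_mean
  baseline_net_imports <- ni

  # first-generation bioenergy baseline: a few percent of cereal and
  # oil-crop food consumption at the base year
  bf <- baseline_consumption[baseline_consumption$commodity %in%
                               c("cereals", "oil_crops"), ]
  bf$tonnes <- bf$tonnes * 0.04
  rownames(bf) <- NULL
  baseline_firstgen <- bf

  fpu_ids <- sort(unique(cells$fpu_id))
  fpus <- data.frame(
    fpu_id = fpu_ids,
    non_ag_frac = runif(length(fpu_ids), 0.10, 0.25),
    reserve_frac = 0.3
  )

  world <- structure(list(
    cells = cells, anchors = anchors, countries = countries,
    trajectories = trajectories,
    baseline_consumption = baseline_consumption,
    baseline_net_imports = baseline_net_imports,
    baseline_firstgen = baseline_firstgen,
    fpus = fpus, demand_offsets = offsets,
    crops = crops, commodities = commodities,
    resolution_deg = res, base_year = AGROSIM_BASE_YEAR
  ), class = "agro_world")
  validate_world(world)
  world
}

#' Validate the invariants of a synthetic world
#'
#' Checks land-cover closure, anchor monotonicity, protection bounds and
#' membership integrity; stops with an informative message on violation.
#'
#' @param world an `agro_world` object.
#' @return `world`, invisibly, if all invariants hold.
#' @export
validate_world <- function(world) {
  cells <- world$cells
  cov_cols <- grep("^cover_", names(cells), value = TRUE)
  s <- rowSums(cells[, cov_cols, drop = FALSE])
  if (any(abs(s - 1) > 1e-9))
    stop("land-cover fractions do not sum to 1 for cells: ",
         paste(head(cells$cell_id[abs(s - 1) > 1e-9]), collapse = ", "))
  if (any(cells[, cov_cols] < -1e-12 | cells[, cov_cols] > 1 + 1e-12))
    stop("land-cover fraction outside [0,1]")
  nat <- cells$cover_forest + cells$cover_natural
  if (any(cells$protected_frac < -1e-12 |
          cells$protected_frac > nat + 1e-9))
    stop("protected fraction outside [0, forest + other natural]")
  an <- world$anchors
  bad <- !(an$y_n200_rf >= an$y_n0_rf - 1e-12 &
           an$y_n1000_rf >= an$y_n200_rf - 1e-12 &
           an$y_n200_ir >= an$y_n0_ir - 1e-12 &
           an$y_n1000_ir >= an$y_n200_ir - 1e-12 &
           an$y_n0_ir >= an$y_n0_rf - 1e-12 &
           an$y_n200_ir >= an$y_n200_rf - 1e-12 &
           an$y_n1000_ir >= an$y_n1000_rf - 1e-12)
  if (any(bad))
    stop("anchor monotonicity violated at ",
         paste(head(paste(an$cell_id[bad], an$crop[bad])), collapse = ", "))
  if (any(an$irrig_req_km3_ha < 0) || any(cells$runoff_km3 < 0))
    stop("negative irrigation requirement or runoff")
  if (anyNA(match(cells$fpu_id, world$fpus$fpu_id)))
    stop("cell references unknown FPU")
  if (anyNA(match(cells$country_id, world$countries$country_id)))
    stop("cell references unknown country")
  invisible(world)
}

#' @export
print.agro_world <- function(x, ...) {
  cat("Synthetic world:", nrow(x$countries), "countries,",
      nrow(x$cells), "cells,", length(x$crops), "crops\n")
  cat("  crops:", paste(x$crops, collapse = ", "), "\n")
  cat("  total land:", format(sum(x$cells$area_ha) / 1e6, digits = 4),
      "Mha; base year", x$base_year, "\n")
  invisible(x)
}

#' Generate a synthetic consumption history
#'
#' Emulates the structure of national historical statistics: GDP per capita,
#' population and per-commodity consumption for the years leading up to the
#' base year.  Per-capita consumption is drawn from the known log-log income
#' relationship (see [demand_truth()]) plus the world's country offsets and
#' multiplicative log-normal noise, so demand-model fitting can be tested
#' against the generating coefficients (stored in the `truth` attribute).
#'
#' @param world an `agro_world`.
#' @param n_years number of historical years ending at the base year (>= 3).
#' @param seed integer seed.
#' @param noise_sd standard deviation of the log-consumption noise; 0 puts
#'   consumption exactly on the generating curve.
#' @param include_offsets apply the world's country-specific dietary offsets
#'   (the realistic case); `FALSE` generates from the global curve alone,
#'   which makes pooled-regression recovery of the generating slope exact in
#'   expectation.
#' @return data.frame (`country_id`, `year`, `gdp_pc`, `population`,
#'   `commodity`, `consumption_t`) with attribute `truth` (coefficients,
#'   offsets, noise_sd).
#' @export
generate_history <- function(world, n_years = 40, seed = 1, noise_sd = 0.08,
                             include_offsets = TRUE) {
  stopifnot(inherits(world, "agro_world"))
  if (!is.numeric(n_years) || n_years < 3)
    stop("n_years must be >= 3", call. = FALSE)
  n_years <- as.integer(n_years)
  set.seed(as.integer(seed))
  years <- (world$base_year - n_years + 1L):world$base_year
  tr <- demand_truth()
  tr <- tr[tr$commodity %in% (world$commodities %||% tr$commodity), ]
  out <- vector("list", nrow(world$countries))
  for (ci in seq_len(nrow(world$countries))) {
    co <- world$countries[ci, ]
    g <- co$gdp_growth + rnorm(n_years, 0, 0.004)
    gdp <- co$gdp_pc_2010 / rev(cumprod(1 + g)) * (1 + g[n_years])
    gdp <- gdp * (co$gdp_pc_2010 / gdp[n_years])  # pin base year exactly
    pop <- co$population_2010 *
      (1 + co$pop_growth)^(years - world$base_year)
    d0 <- world$demand_offsets[world$demand_offsets$country_id ==
                                 co$country_id, ]
    grid <- expand.grid(year = years, commodity = tr$commodity,
                        stringsAsFactors = FALSE)
    grid$country_id <- co$country_id
    grid$gdp_pc <- gdp[match(grid$year, years)]
    grid$population <- pop[match(grid$year, years)]
    ab <- tr[match(grid$commodity, tr$commodity), ]
    dd <- if (include_offsets) d0$d0[match(grid$commodity, d0$commodity)]
          else 0
    eps <- rnorm(nrow(grid), 0, noise_sd)
    grid$consumption_t <- exp(ab$a + ab$b * log(grid$gdp_pc) + dd + eps) *
      grid$population
    out[[ci]] <- grid
  }
  hist <- do.call(rbind, out)[, c("country_id", "year", "gdp_pc",
                                  "population", "commodity",
                                  "consumption_t")]
  rownames(hist) <- NULL
  attr(hist, "truth") <- list(coef = tr, offsets = world$demand_offsets,
                              noise_sd = noise_sd)
  hist
}

#' Moran's I spatial autocorrelation with inverse-distance weights
#'
#' Used to verify that generated fields are spatially autocorrelated within
#' a country.
#'
#' @param values numeric field values per cell.
#' @param lat,lon cell-centre coordinates (degrees).
#' @return Moran's I statistic (expected ~ -1/(n-1) under no correlation).
#' @export
morans_i <- function(values, lat, lon) {
  n <- length(values)
  stopifnot(n > 2, length(lat) == n, length(lon) == n)
  d <- sqrt(outer(lat, lat, "-")^2 + outer(lon, lon, "-")^2)
  w <- 1 / pmax(d, 1e-9)
  diag(w) <- 0
  z <- values - mean(values)
  (n / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
}
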