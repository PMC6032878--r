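#' Read and write worlds, configs and run outputs
#'
#' Gridded variables are written as long-format CSV on the lat/lon lattice
#' with a JSON metadata sidecar carrying units, grid resolution and the
#' coordinate convention (cell centres; a cell owns `[lon, lon + res)`);
#' tabular artifacts are plain CSV.  Numeric values are serialised with 17
#' significant digits so write-then-read is the identity to full double
#' precision, and all writers are deterministic.
#'
#' @name io_formats
NULL

WORLD_SCHEMA <- list(
  cells = c("cell_id", "lat", "lon", "area_ha", "country_id", "fpu_id",
            "protected_frac", "aridity", "runoff_km3", "pasture_yield"),
  anchors = c("cell_id", "crop", "y_n0_rf", "y_n200_rf", "y_n1000_rf",
              "y_n0_ir", "y_n200_ir", "y_n1000_ir", "irrig_req_km3_ha"),
  countries = c("country_id", "gdp_pc_2010", "population_2010",
                "gdp_growth", "pop_growth"),
  trajectories = c("country_id", "year", "gdp_pc", "population"),
  baseline_consumption = c("country_id", "commodity", "tonnes"),
  baseline_net_imports = c("country_id", "commodity", "tonnes"),
  baseline_firstgen = c("country_id", "commodity", "tonnes"),
  fpus = c("fpu_id", "non_ag_frac", "reserve_frac"),
  demand_offsets = c("country_id", "commodity", "d0")
)

write_table_precise <- function(df, path) {
  out <- df
  for (v in names(out))
    if (is.numeric(out[[v]]) && !is.integer(out[[v]]))
      out[[v]] <- sprintf("%.17g", out[[v]])
  data.table::fwrite(out, path)
}

read_table_precise <- function(path, character_cols) {
  df <- as.data.frame(data.table::fread(path, colClasses = "character"))
  for (v in setdiff(names(df), character_cols))
    df[[v]] <- as.numeric(df[[v]])
  if ("year" %in% names(df)) df$year <- as.integer(df$year)
  df
}

#' @rdname io_formats
#' @param world an `agro_world`.
#' @param path directory to write into (created if missing).
#' @return `write_world()`: `path`, invisibly.
#' @export
write_world <- function(world, path) {
  stopifnot(inherits(world, "agro_world"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(WORLD_SCHEMA))
    write_table_precise(world[[nm]], file.path(path, paste0(nm, ".csv")))
  meta <- list(
    format = "agrosim-world", version = 1L,
    crops = world$crops, commodities = world$commodities,
    resolution_deg = world$resolution_deg, base_year = world$base_year,
    grid_convention = "cell centres at odd multiples of resolution/2; a cell owns [lon, lon+res)",
    units = list(area_ha = "ha", yields = "t/ha", runoff_km3 = "km3/yr",
                 irrig_req_km3_ha = "km3/ha/yr", gdp_pc = "2010 US$/person",
                 tonnes = "t/yr", currency = "2010 US$")
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io_formats
#' @return `read_world()`: the reconstructed, validated `agro_world`.
#' @export
read_world <- function(path) {
  meta_path <- file.path(path, "meta.json")
  errors <- character(0)
  if (!file.exists(meta_path)) errors <- c(errors, "missing meta.json")
  parts <- list()
  char_cols <- c("cell_id", "crop", "country_id", "fpu_id", "commodity")
  for (nm in names(WORLD_SCHEMA)) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) { errors <- c(errors, paste("missing file:", nm)); next }
    df <- read_table_precise(f, char_cols)
    miss <- setdiff(WORLD_SCHEMA[[nm]], names(df))
    if (length(miss))
      errors <- c(errors, paste0(nm, ": missing column(s) ",
                                 paste(miss, collapse = ", ")))
    parts[[nm]] <- df
  }
  if (length(errors))
    stop("invalid world at ", path, ":\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  world <- structure(c(parts, list(
    crops = meta$crops, commodities = meta$commodities,
    resolution_deg = meta$resolution_deg,
    base_year = as.integer(meta$base_year))), class = "agro_world")
  validate_world(world)
  world
}

#' Validate a scenario configuration file
#'
#' Reads a YAML scenario file, merges it over the defaults and validates
#' every field (ranges and cross-field rules) before any computation;
#' violations are aggregated into a single error listing every failing
#' field.
#'
#' @param path YAML file, or a list already in memory.
#' @return a validated `scenario_config`.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- do.call(default_config, raw %||% list())
  e <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) e <<- c(e, msg)
  chk(cfg$years$start >= 2010 && cfg$years$end <= 2100,
      "years: start >= 2010 and end <= 2100")
  chk(cfg$years$end >= cfg$years$start, "years: end >= start")
  chk(cfg$yield_avg_window >= 1, "yield_avg_window: must be >= 1")
  chk(cfg$spinup$threshold > 0, "spinup$threshold: must be > 0")
  chk(cfg$spinup$max_iter >= 1, "spinup$max_iter: must be >= 1")
  chk(cfg$market$lambda > 0, "market$lambda: must be > 0")
  chk(all(unlist(cfg$market$prices) > 0), "market$prices: must be > 0")
  chk(cfg$market$stocks_to_use >= 0, "market$stocks_to_use: must be >= 0")
  chk(cfg$ensemble$n >= 1, "ensemble$n: must be >= 1")
  chk(cfg$ensemble$half_width >= 0 && cfg$ensemble$half_width <= 1,
      "ensemble$half_width: must be in [0, 1] (sampled parameters cannot go negative)")
  chk(cfg$demand$history_years >= 3, "demand$history_years: must be >= 3")
  chk(cfg$demand$convergence_rate >= 0, "demand$convergence_rate: must be >= 0")
  chk(cfg$world$n_countries >= 1 && cfg$world$cells_per_country >= 1,
      "world: n_countries and cells_per_country must be >= 1")
  cost_err <- tryCatch({ do.call(default_costs, cfg$costs); NULL },
                       error = function(err) conditionMessage(err))
  if (!is.null(cost_err)) e <- c(e, paste("costs:", cost_err))
  if (length(e))
    stop("invalid configuration:\n  ", paste(e, collapse = "\n  "),
         call. = FALSE)
  cfg
}

#' Write scenario run outputs
#'
#' Writes the global, market and country time series as tidy CSV, decadal
#' per-cell land-cover maps as long-format CSV, and a JSON run manifest
#' (configuration snapshot, seed, package version, invariant audit) that
#' suffices to reproduce the run.
#'
#' @param run an `agro_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "agro_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_precise(run$global, file.path(dir, "global.csv"))
  write_table_precise(run$market, file.path(dir, "market.csv"))
  write_table_precise(run$countries, file.path(dir, "countries.csv"))
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  for (y in names(run$maps))
    write_table_precise(run$maps[[y]],
                        file.path(dir, "maps", paste0("cells_", y, ".csv")))
  closure <- max(abs(rowSums(
    run$state$world$cells[, grep("^cover_",
                                 names(run$state$world$cells))]) - 1))
  manifest <- list(
    package = "agrosim",
    version = as.character(utils::packageVersion("agrosim")),
    config = unclass(run$config),
    spinup = run$spinup,
    audit = list(max_cover_closure_error = closure),
    currency = "2010 US$"
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
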