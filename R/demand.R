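#' Fit the income-driven demand model
#'
#' Per commodity group, regresses `ln(per-capita consumption)` on
#' `ln(per-capita GDP)` across countries and years, weighting data points by
#' population, and records each country's base-year offset from the global
#' curve (the cultural difference between observed and curve-implied
#' consumption).  Positive slopes give income-elastic groups (livestock);
#' negative slopes give staples that decline, at a decreasing rate and
#' bounded below by zero, as income rises.
#'
#' @param history data.frame with columns `country_id`, `year`, `gdp_pc`,
#'   `population`, `commodity`, `consumption_t` (see [generate_history()]).
#' @param base_year year at which country offsets are evaluated; defaults to
#'   the last year present.
#' @param convergence_rate offset-shrinkage rate per unit of log-income
#'   growth (kappa >= 0), stored for [project_demand()].
#' @return object of class `demand_model` with components `coef` (commodity,
#'   a, b, se_b, n), `offsets` (country_id, commodity, d0), `base_gdp`
#'   (country_id, gdp_pc), `base_year`, `convergence_rate`.
#' @export
fit_demand_model <- function(history, base_year = NULL,
                             convergence_rate = 1.0) {
  need <- c("country_id", "year", "gdp_pc", "population", "commodity",
            "consumption_t")
  if (!all(need %in% names(history)))
    stop("history missing columns: ",
         paste(setdiff(need, names(history)), collapse = ", "), call. = FALSE)
  h <- history
  drop <- !(h$gdp_pc > 0 & h$consumption_t > 0 & h$population > 0)
  if (any(drop)) {
    warning(sum(drop), " rows with non-positive income/consumption dropped")
    h <- h[!drop, ]
  }
  if (!nrow(h)) stop("no usable rows after dropping non-positive data",
                     call. = FALSE)
  if (is.null(base_year)) base_year <- max(h$year)

  coefs <- do.call(rbind, lapply(split(h, h$commodity), function(d) {
    if (length(unique(d$gdp_pc)) < 2)
      stop("commodity ", d$commodity[1], ": need >= 2 distinct income levels",
           call. = FALSE)
    y <- log(d$consumption_t / d$population)
    x <- log(d$gdp_pc)
    fit <- lm(y ~ x, weights = d$population)
    data.frame(commodity = d$commodity[1],
               a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
               se_b = summary(fit)$coefficients[2, 2], n = nrow(d))
  }))
  rownames(coefs) <- NULL

  base <- h[h$year == base_year, ]
  if (!nrow(base)) stop("no history rows at base year ", base_year,
                        call. = FALSE)
  ab <- coefs[match(base$commodity, coefs$commodity), ]
  offsets <- data.frame(
    country_id = base$country_id, commodity = base$commodity,
    d0 = log(base$consumption_t / base$population) -
      (ab$a + ab$b * log(base$gdp_pc))
  )
  base_gdp <- unique(base[, c("country_id", "gdp_pc")])

  structure(list(coef = coefs, offsets = offsets, base_gdp = base_gdp,
                 base_year = base_year, convergence_rate = convergence_rate),
            class = "demand_model")
}

#' @export
print.demand_model <- function(x, ...) {
  cat("Demand model (log-log, population-weighted), base year",
      x$base_year, "\n")
  print(x$coef, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.demand_model <- function(object, ...) object$coef

#' Project food demand
#'
#' Per-capita demand is `exp(a + b ln(gdp_pc) + d(t))`; totals multiply by
#' population.  With dietary convergence on, the country offset shrinks
#' exponentially with realised log-income growth above the base year,
#' `d(t) = d0 exp(-kappa * max(0, ln gdp_t - ln gdp_base))`, pulling diets
#' towards the global curve as countries grow richer; with convergence off
#' the offset is held constant.
#'
#' @param model a `demand_model`.
#' @param year projection year (>= base year).
#' @param gdp_pc data.frame (`country_id`, `gdp_pc`) at `year`.
#' @param population data.frame (`country_id`, `population`) at `year`.
#' @param convergence_on logical flag.
#' @return data.frame (`country_id`, `commodity`, `percap_t`, `tonnes`).
#' @export
project_demand <- function(model, year, gdp_pc, population,
                           convergence_on = FALSE) {
  stopifnot(inherits(model, "demand_model"))
  if (year < model$base_year)
    stop("projection year before base year", call. = FALSE)
  if (any(population$population < 0))
    stop("negative population", call. = FALSE)
  d <- model$offsets
  d$gdp_pc <- gdp_pc$gdp_pc[match(d$country_id, gdp_pc$country_id)]
  d$population <- population$population[match(d$country_id,
                                              population$country_id)]
  if (anyNA(d$gdp_pc) || anyNA(d$population))
    stop("gdp_pc/population missing for some model countries", call. = FALSE)
  ab <- model$coef[match(d$commodity, model$coef$commodity), ]
  dt <- d$d0
  if (convergence_on) {
    g0 <- model$base_gdp$gdp_pc[match(d$country_id,
                                      model$base_gdp$country_id)]
    growth <- pmax(0, log(d$gdp_pc) - log(g0))
    dt <- d$d0 * exp(-model$convergence_rate * growth)
  }
  percap <- exp(ab$a + ab$b * log(d$gdp_pc) + dt)
  data.frame(country_id = d$country_id, commodity = d$commodity,
             percap_t = percap, tonnes = percap * d$population)
}

#' Exogenous bioenergy demand trajectories
#'
#' First-generation bioenergy (fuel from food commodities) rises linearly
#' from its 2010 baseline to double that level by 2030 and is constant
#' thereafter.  Second-generation demand for dedicated energy crops is a
#' global trajectory rising linearly from 34 Mt DM/yr in 2010 to
#' 4,000 Mt DM/yr in 2100; it is not assigned to countries.
#'
#' @param year calendar year in \[2010, 2100\].
#' @param baseline_firstgen data.frame (`country_id`, `commodity`, `tonnes`)
#'   of first-generation bioenergy demand at 2010; may be `NULL` for none.
#' @return list with `firstgen` (same shape as the baseline, scaled) and
#'   `secondgen_t` (global tonnes DM/yr of energy crops).
#' @export
bioenergy_demand <- function(year, baseline_firstgen = NULL) {
  if (year < 2010 || year > 2100)
    stop("year must be within 2010..2100", call. = FALSE)
  mult <- 1 + pmin(pmax(year - 2010, 0), 20) / 20   # doubles by 2030
  firstgen <- baseline_firstgen
  if (!is.null(firstgen)) firstgen$tonnes <- firstgen$tonnes * mult
  secondgen <- (34 + (4000 - 34) * (year - 2010) / 90) * 1e6  # Mt -> t
  list(firstgen = firstgen, secondgen_t = secondgen)
}
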