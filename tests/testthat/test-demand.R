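two_point_history <- function() {
  data.frame(country_id = rep(c("A", "B"), each = 2),
             year = rep(c(2009, 2010), 2),
             gdp_pc = c(1000, 1000, 20000, 20000),
             population = 1e6,
             commodity = "cereals",
             consumption_t = exp(-2 + 0.2 * log(c(1000, 1000, 20000,
                                                  20000))) * 1e6)
}

test_that("an exact log-linear history is recovered exactly", {
  m <- fit_demand_model(two_point_history())
  expect_equal(m$coef$a, -2, tolerance = 1e-10)
  expect_equal(m$coef$b, 0.2, tolerance = 1e-10)
  # countries on the curve have zero base-year offset
  expect_equal(m$offsets$d0, c(0, 0), tolerance = 1e-10)
})

test_that("fitting on generated history recovers slopes within 3 SE", {
  w <- fx_world_small()
  h <- generate_history(w, n_years = 40, seed = 8, include_offsets = FALSE)
  m <- fit_demand_model(h)
  tr <- demand_truth()
  for (i in seq_len(nrow(m$coef))) {
    b_true <- tr$b[tr$commodity == m$coef$commodity[i]]
    expect_lt(abs(m$coef$b[i] - b_true), 3 * m$coef$se_b[i])
  }
})

test_that("zero rows are dropped with a warning and empty data errors", {
  h <- two_point_history()
  h$consumption_t[1] <- 0
  expect_warning(fit_demand_model(h), "dropped")
  h$consumption_t <- 0
  expect_error(suppressWarnings(fit_demand_model(h)), "no usable rows")
})

test_that("projection responds to population, income and convergence", {
  w <- fx_world_small()
  h <- generate_history(w, n_years = 30, seed = 9)
  m <- fit_demand_model(h, convergence_rate = 1)
  gdp <- data.frame(country_id = w$countries$country_id,
                    gdp_pc = w$countries$gdp_pc_2010)
  pop <- data.frame(country_id = w$countries$country_id,
                    population = w$countries$population_2010)

  p1 <- project_demand(m, 2020, gdp, pop)
  pop2 <- pop; pop2$population <- 2 * pop2$population
  p2 <- project_demand(m, 2020, gdp, pop2)
  expect_equal(p2$tonnes, 2 * p1$tonnes, tolerance = 1e-12)

  # constant income and population, convergence off: demand is constant
  p3 <- project_demand(m, 2040, gdp, pop)
  expect_equal(p3$tonnes, p1$tonnes, tolerance = 1e-12)

  # near-infinite convergence puts every country on the global curve
  m_inf <- m; m_inf$convergence_rate <- 1e6
  gdp_up <- gdp; gdp_up$gdp_pc <- gdp$gdp_pc * 2
  p4 <- project_demand(m_inf, 2030, gdp_up, pop, convergence_on = TRUE)
  ab <- m$coef[match(p4$commodity, m$coef$commodity), ]
  on_curve <- exp(ab$a + ab$b * log(gdp_up$gdp_pc[
    match(p4$country_id, gdp_up$country_id)]))
  expect_equal(p4$percap_t, on_curve, tolerance = 1e-6)
})

test_that("convergence shrinks offsets monotonically without sign flips", {
  w <- fx_world_small()
  h <- generate_history(w, n_years = 30, seed = 9)
  m <- fit_demand_model(h, convergence_rate = 0.8)
  pop <- data.frame(country_id = w$countries$country_id,
                    population = w$countries$population_2010)
  gdp0 <- data.frame(country_id = w$countries$country_id,
                     gdp_pc = w$countries$gdp_pc_2010)
  prev_dev <- NULL
  for (mult in c(1, 1.5, 2.5, 4)) {
    gdp <- gdp0; gdp$gdp_pc <- gdp0$gdp_pc * mult
    p <- project_demand(m, 2030, gdp, pop, convergence_on = TRUE)
    ab <- m$coef[match(p$commodity, m$coef$commodity), ]
    dev <- log(p$percap_t) - (ab$a + ab$b * log(gdp$gdp_pc[
      match(p$country_id, gdp$country_id)]))
    if (!is.null(prev_dev)) {
      expect_true(all(abs(dev) <= abs(prev_dev) + 1e-12))
      expect_true(all(sign(dev) == sign(prev_dev) | dev == 0))
    }
    prev_dev <- dev
  }
})

test_that("projection rejects invalid inputs", {
  m <- fit_demand_model(two_point_history())
  gdp <- data.frame(country_id = c("A", "B"), gdp_pc = c(1000, 20000))
  pop <- data.frame(country_id = c("A", "B"), population = c(-1, 1e6))
  expect_error(project_demand(m, 2020, gdp, pop), "population")
  pop$population <- 1e6
  expect_error(project_demand(m, 2000, gdp, pop), "base year")
})

test_that("bioenergy trajectories match their stated endpoints", {
  base <- data.frame(country_id = "A", commodity = "cereals", tonnes = 100)
  b2010 <- bioenergy_demand(2010, base)
  expect_equal(b2010$firstgen$tonnes, 100)
  expect_equal(b2010$secondgen_t, 34e6)
  expect_equal(bioenergy_demand(2020, base)$firstgen$tonnes, 150)
  expect_equal(bioenergy_demand(2030, base)$firstgen$tonnes, 200)
  expect_equal(bioenergy_demand(2050, base)$firstgen$tonnes, 200)
  expect_equal(bioenergy_demand(2100, base)$secondgen_t, 4000e6)
  expect_error(bioenergy_demand(2005), "2010")
  expect_error(bioenergy_demand(2101), "2100")
})

test_that("fit on early history projects the later period within noise", {
  # split-sample benchmark: calibrate on the first two-thirds, project the
  # remainder, compare against the generating curve
  w <- fx_world_small()
  noise_sd <- 0.08
  h <- generate_history(w, n_years = 45, seed = 10, noise_sd = noise_sd)
  split_year <- sort(unique(h$year))[30]
  m <- fit_demand_model(h[h$year <= split_year, ], base_year = split_year)
  late <- h[h$year > split_year, ]
  for (yr in unique(late$year)) {
    d <- late[late$year == yr, ]
    gdp <- unique(d[, c("country_id", "gdp_pc")])
    pop <- unique(d[, c("country_id", "population")])
    p <- project_demand(m, yr, gdp, pop)
    obs <- d$consumption_t[match(paste(p$country_id, p$commodity),
                                 paste(d$country_id, d$commodity))]
    log_err <- abs(log(p$tonnes) - log(obs))
    expect_lt(mean(log_err), 3 * noise_sd)
  }
})
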