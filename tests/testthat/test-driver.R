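test_that("spin-up terminates below the convergence threshold", {
  st <- fx_spun_small()
  expect_true(st$spinup$converged)
  expect_lt(st$spinup$terminal_change, 0.004)
  expect_gte(st$spinup$iterations, 1)
})

test_that("spin-up is idempotent: rerunning on its own output converges fast", {
  st <- fx_spun_small()
  st2 <- spin_up(st)
  expect_true(st2$spinup$converged)
  expect_lte(st2$spinup$iterations, 3)
  expect_lt(st2$spinup$terminal_change, 0.004)
})

test_that("non-convergence warns and flags the state", {
  w <- generate_world(2, 9, n_crops = 3, seed = 7)
  cfg <- fx_cfg_small()
  st <- initialise_simulation(w, cfg)
  expect_warning(st1 <- spin_up(st, max_iter = 1), "did not converge")
  expect_false(st1$spinup$converged)
})

test_that("a yield-averaging window is inert for constant anchors", {
  st <- fx_spun_small()
  anchors <- st$world$anchors
  series <- function(year) anchors
  st1 <- st; st1$config$yield_avg_window <- 1
  st5 <- st; st5$config$yield_avg_window <- 5
  r1 <- run_timestep(st1, 2011, anchor_series = series)
  r5 <- run_timestep(st5, 2011, anchor_series = series)
  expect_equal(r1$market$last_flows, r5$market$last_flows)
  expect_equal(agrosim:::solution_matrix(r1$solutions),
               agrosim:::solution_matrix(r5$solutions))
  # and averaging distinct sets really averages
  a2 <- anchors; a2$y_n200_rf <- a2$y_n200_rf + 2
  avg <- average_anchor_sets(list(anchors, a2))
  expect_equal(avg$y_n200_rf, anchors$y_n200_rf + 1)
})

test_that("raising one country's demand raises world supply of that good", {
  st <- fx_spun_small()
  base <- run_timestep(st, 2011)
  st_hi <- st
  tr <- st_hi$world$trajectories
  sel <- tr$country_id == "C01" & tr$year == 2011
  tr$population[sel] <- tr$population[sel] * 1.3
  st_hi$world$trajectories <- tr
  hi <- run_timestep(st_hi, 2011)
  draw <- function(run) {
    f <- run$market$last_flows
    prod <- sum(vapply(run$solutions, function(s)
      s$production["cereals"] %||% 0, 0))
    stock_draw <- st$market$stocks[["cereals"]] -
      f$stock_t[f$commodity == "cereals"]
    prod + stock_draw
  }
  expect_gt(draw(hi), draw(base))
})

test_that("a converged state barely moves under constant drivers", {
  run <- fx_run_constant()
  g <- run$global
  a <- g$cropland_Mha[g$year == 2015]
  b <- g$cropland_Mha[g$year == 2025]
  expect_lt(abs(b - a) / a, 0.01)  # < 1% per decade
  ap <- g$pasture_Mha[g$year == 2015]
  bp <- g$pasture_Mha[g$year == 2025]
  expect_lt(abs(bp - ap) / ap, 0.01)
})

test_that("scenarios are deterministic and handle end == start", {
  cfg <- fx_cfg_small()
  cfg$years$end <- 2010
  one <- run_scenario(cfg)
  expect_equal(nrow(one$global), 1)
  expect_equal(one$global$year, 2010)

  r1 <- fx_run_small()
  r2 <- run_scenario(fx_cfg_small())
  expect_identical(r1$global, r2$global)
  expect_identical(r1$market, r2$market)
  expect_identical(r1$maps, r2$maps)
})

test_that("land cover closes and commodity accounting balances every year", {
  run <- fx_run_small()
  for (y in names(run$maps)) {
    cov <- run$maps[[y]][, grep("^cover_", names(run$maps[[y]]))]
    expect_true(all(abs(rowSums(cov) - 1) < 1e-9))
  }
  f <- run$market
  for (cm in unique(f$commodity)) {
    d <- f[f$commodity == cm, ]
    d <- d[order(d$year), ]
    for (i in 2:nrow(d)) {
      # stock' = max(0, stock + oversupply), shortfall logged as unmet
      expected <- d$stock_t[i - 1] + d$oversupply_t[i]
      expect_equal(d$stock_t[i], max(0, expected), tolerance = 1e-6)
      if (expected < 0)
        expect_equal(d$unmet_t[i], -expected, tolerance = 1e-6)
      # price always moves against the imbalance (skip negligible flows
      # whose price step underflows double precision)
      if (abs(d$oversupply_t[i]) > 1) {
        prev_price <- if (i == 2) d$price[1] else d$price[i - 1]
        expect_equal(sign(d$price[i] - prev_price),
                     -sign(d$oversupply_t[i]))
      }
    }
  }
})

test_that("ensembles are reproducible, bounded and widen with half-width", {
  cfg <- default_config(world = list(n_countries = 2,
                                     cells_per_country = 9, n_crops = 3),
                        years = list(start = 2010, end = 2012),
                        ensemble = list(n = 4, half_width = 0.5), seed = 5)
  e0 <- run_ensemble(cfg, n = 3, half_width = 0)
  g <- split(e0$members, e0$members$member)
  expect_equal(g[[1]]$cropland_Mha, g[[2]]$cropland_Mha)
  expect_equal(g[[2]]$cropland_Mha, g[[3]]$cropland_Mha)

  central <- unlist(default_costs()[agrosim:::ensemble_parameters()])
  e5 <- run_ensemble(cfg, n = 4, half_width = 0.5)
  for (p in colnames(e5$samples)) {
    expect_true(all(e5$samples[, p] >= central[[p]] * 0.5 - 1e-9))
    expect_true(all(e5$samples[, p] <= central[[p]] * 1.5 + 1e-9))
  }

  disp <- vapply(c(0.1, 0.5), function(h) {
    e <- run_ensemble(cfg, n = 4, half_width = h)
    last <- e$members[e$members$year == 2012, ]
    stats::sd(last$cropland_Mha)
  }, 0)
  expect_lte(disp[1], disp[2] + 1e-9)
  expect_error(run_ensemble(cfg, n = 4, half_width = 1.5), "half_width")
})
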