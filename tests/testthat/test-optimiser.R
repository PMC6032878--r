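test_that("zero demand with no existing agriculture costs nothing", {
  cl <- make_test_clusters(cropland_ha = c(0, 0), pasture_ha = c(0, 0))
  surf <- cluster_surfaces(cl)
  dem <- c(cereals = 0, ruminant = 0, monogastric = 0)
  pr <- c(cereals = 200, ruminant = 3000, monogastric = 1800)
  sol <- optimise_country(cl, surf, dem, pr, default_costs(),
                          export_caps = setNames(rep(0, 3), names(pr)))
  expect_equal(sum(sol$summary$area_ha), 0)
  expect_equal(sol$objective, 0)
})

test_that("single-cluster demand matches the brute-force lattice optimum", {
  cl <- make_test_clusters(yield_mult = 1, cropland_ha = 1e5,
                           pasture_ha = 0, avail_natural_ha = 2e5,
                           water_km3 = 10)
  surf <- cluster_surfaces(cl)
  costs <- default_costs()
  # demand below zero-input capacity on existing cropland; imports priced
  # prohibitively so production is domestic
  dem <- c(cereals = 1e5)
  pr <- c(cereals = 1e6)
  sol <- optimise_country(cl, surf, dem, pr, costs,
                          export_caps = c(cereals = 0))
  validate_solution(sol, cl, costs)
  expect_gte(sum(sol$production["cereals"]), dem["cereals"] * (1 - 1e-9))
  oracle <- lattice_oracle(cl, surf, dem[["cereals"]], costs)
  expect_lte(sol$objective, oracle * 1.02)
})

test_that("two-cluster instances stay within 2% of the lattice oracle", {
  for (case in list(list(ym = c(1, 1), d = 5e5), list(ym = c(1.6, 0.8),
                                                      d = 8e5),
                    list(ym = c(0.7, 1.3), d = 1.2e6))) {
    cl <- make_test_clusters(yield_mult = case$ym,
                             cropland_ha = c(6e4, 6e4),
                             pasture_ha = c(0, 0),
                             avail_natural_ha = c(1.5e5, 1.5e5))
    surf <- cluster_surfaces(cl)
    costs <- default_costs()
    dem <- c(cereals = case$d)
    pr <- c(cereals = 1e6)
    sol <- optimise_country(cl, surf, dem, pr, costs,
                            export_caps = c(cereals = 0))
    validate_solution(sol, cl, costs)
    oracle <- lattice_oracle(cl, surf, case$d, costs)
    expect_lte(sol$objective, oracle * 1.02)
    expect_gte(sum(sol$production["cereals"]), case$d * (1 - 1e-9))
  }
})

test_that("expansion goes to the dominant cluster first", {
  cl <- make_test_clusters(yield_mult = c(2, 1), cropland_ha = c(2e4, 2e4),
                           pasture_ha = c(0, 0),
                           avail_natural_ha = c(1e5, 1e5))
  surf <- cluster_surfaces(cl)
  # demand beyond what existing cropland can carry even fully intensified
  dem <- c(cereals = 1.2e6)
  sol <- optimise_country(cl, surf, dem, c(cereals = 1e6), default_costs(),
                          export_caps = c(cereals = 0))
  a <- sol$activities
  ex <- a[a$tier == "expansion", ]
  exp_k1 <- sum(ex$area_ha[ex$cluster_id == "T01_k1"])
  exp_k2 <- sum(ex$area_ha[ex$cluster_id == "T01_k2"])
  # demand forces some expansion, and the low-yield cluster expands only
  # once the dominant cluster's convertible land is exhausted
  expect_gt(exp_k1, 0)
  expect_true(exp_k2 <= 1 || exp_k1 >= cl$table$avail_natural_ha[1] - 1)
})

test_that("raising a commodity's price never lowers domestic production", {
  cl <- make_test_clusters(cropland_ha = c(8e4, 8e4))
  surf <- cluster_surfaces(cl)
  costs <- default_costs()
  dem <- c(cereals = 3e5, ruminant = 1e4, monogastric = 2e4)
  prods <- vapply(c(100, 200, 400, 800), function(p) {
    sol <- optimise_country(cl, surf, dem,
                            c(cereals = p, ruminant = 3000,
                              monogastric = 1800), costs,
                            export_caps = c(cereals = 2e5, ruminant = 0,
                                            monogastric = 0))
    sum(sol$production["cereals"])
  }, 0)
  expect_true(all(diff(prods) >= -1e-6))
})

test_that("dearer conversion reduces expansion and raises intensity", {
  mk <- function(conv) {
    costs <- default_costs(conv_cost_nat_ag = conv)
    cl <- make_test_clusters(cropland_ha = c(3e4, 3e4),
                             pasture_ha = c(0, 0))
    surf <- cluster_surfaces(cl)
    sol <- optimise_country(cl, surf, c(cereals = 6e5),
                            c(cereals = 1e6), costs,
                            export_caps = c(cereals = 0))
    a <- sol$activities
    list(expansion = sum(a$area_ha[a$tier == "expansion"]),
         mean_fert = weighted.mean(a$fert, a$area_ha))
  }
  cheap <- mk(500); dear <- mk(4000)
  expect_lte(dear$expansion, cheap$expansion + 1e-6)
  expect_gte(dear$mean_fert, cheap$mean_fert - 1e-9)
})

test_that("the deforestation cap binds national expansion", {
  cl <- make_test_clusters(cropland_ha = c(1e4, 1e4), pasture_ha = c(0, 0),
                           avail_natural_ha = c(2e5, 2e5))
  surf <- cluster_surfaces(cl)
  costs <- default_costs()
  dem <- c(cereals = 3e5)
  sol_free <- optimise_country(cl, surf, dem, c(cereals = 400), costs,
                               china = FALSE)
  sol_cap <- optimise_country(cl, surf, dem, c(cereals = 400), costs,
                              china = TRUE)
  cap_ha <- 2 * costs$china_deforestation_cap * cl$table$forest_ha
  a <- sol_cap$activities
  exp_by_cluster <- tapply(a$area_ha[a$tier == "expansion"],
                           a$cluster_id[a$tier == "expansion"], sum)
  for (j in names(exp_by_cluster))
    expect_lte(exp_by_cluster[[j]],
               cap_ha[match(j, cl$table$cluster_id)] + 1e-6)
  validate_solution(sol_cap, cl, costs)
})

test_that("infeasible fixed-trade targets raise a named error", {
  cl <- make_test_clusters(cropland_ha = c(100, 100),
                           pasture_ha = c(0, 0),
                           avail_natural_ha = c(10, 10))
  surf <- cluster_surfaces(cl)
  dem <- c(cereals = 1e9)
  expect_error(
    optimise_country(cl, surf, dem, c(cereals = 200), default_costs(),
                     net_imports = c(cereals = 0)),
    "infeasible")
})

test_that("every returned solution passes the six feasibility audits", {
  st <- fx_spun_small()
  for (sol in st$solutions) {
    cl <- agrosim:::subset_clusters(st$clusters, sol$country_id)
    expect_true(validate_solution(sol, cl, st$costs))
    # water never exceeded at FPU level either (equal per-cell shares)
    expect_true(all(unlist(sol$water_used) >= -1e-12))
  }
})
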