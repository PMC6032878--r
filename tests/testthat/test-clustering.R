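test_that("limit cases: singleton clusters and a single cluster", {
  w <- fx_world_small()
  cid <- "C01"
  n <- sum(w$cells$country_id == cid)
  m_all <- cluster_country(w, cid, k = n, seed = 1)
  expect_equal(length(unique(m_all$cluster_id)), n)
  m_one <- cluster_country(w, cid, k = 1, seed = 1)
  expect_equal(length(unique(m_one$cluster_id)), 1)
  cl <- aggregate_clusters(w, m_one)
  # one cluster aggregates the whole country
  expect_equal(cl$table$area_ha, sum(w$cells$area_ha[
    w$cells$country_id == cid]))
  expect_error(cluster_country(w, cid, k = n + 1), "k must be")
})

test_that("k-means matches the exhaustive best 2-partition on 8 cells", {
  w <- generate_world(1, 8, n_crops = 2, seed = 3)
  cid <- "C01"
  mem <- cluster_country(w, cid, k = 2, seed = 5)
  cells <- w$cells[order(w$cells$cell_id), ]
  feats <- agrosim:::cluster_features(w, cells)
  wss <- function(assign) {
    s <- 0
    for (g in unique(assign)) {
      m <- feats[assign == g, , drop = FALSE]
      s <- s + sum(sweep(m, 2, colMeans(m))^2)
    }
    s
  }
  got <- wss(mem$cluster_id[match(cells$cell_id, mem$cell_id)])
  # brute force over all 2^7 - 1 bipartitions
  best <- Inf
  for (code in 1:127) {
    assign <- c(0, as.integer(intToBits(code)[1:7]))
    best <- min(best, wss(assign))
  }
  expect_lt(got, best + 1e-8)
})

test_that("cluster count rises with heterogeneity and collapses when flat", {
  w1 <- generate_world(1, 1, n_crops = 2, seed = 1)
  expect_equal(choose_k(w1, "C01"), 1L)

  w <- generate_world(1, 100, n_crops = 2, seed = 4)
  k_het <- choose_k(w, "C01")
  expect_gt(k_het, 1)
  # homogeneous clone: identical anchors everywhere
  w_flat <- w
  for (v in grep("^y_", names(w_flat$anchors), value = TRUE))
    w_flat$anchors[[v]] <- stats::ave(w_flat$anchors[[v]],
                                      w_flat$anchors$crop)
  expect_equal(choose_k(w_flat, "C01"), 1L)
})

test_that("clustering partitions the country and is order-invariant", {
  w <- fx_world_small()
  for (cid in w$countries$country_id) {
    mem <- cluster_country(w, cid, seed = 2)
    cells <- w$cells$cell_id[w$cells$country_id == cid]
    expect_setequal(mem$cell_id, cells)
    expect_equal(anyDuplicated(mem$cell_id), 0)
  }
  # permuting cell order leaves the assignment unchanged (canonical sort)
  w_shuf <- w
  set.seed(1)
  w_shuf$cells <- w$cells[sample(nrow(w$cells)), ]
  expect_equal(cluster_country(w, "C02", seed = 9),
               cluster_country(w_shuf, "C02", seed = 9))
})

test_that("cluster aggregates equal the sum over members", {
  w <- fx_world_small()
  mem <- cluster_country(w, "C01", k = 3, seed = 1)
  water <- world_water_budget(w)
  cl <- aggregate_clusters(w, mem, water)
  cells <- w$cells[w$cells$country_id == "C01", ]
  cells$cluster <- mem$cluster_id[match(cells$cell_id, mem$cell_id)]
  for (j in cl$table$cluster_id) {
    sub <- cells[cells$cluster == j, ]
    row <- cl$table[cl$table$cluster_id == j, ]
    expect_equal(row$area_ha, sum(sub$area_ha))
    expect_equal(row$area_pasture, sum(sub$cover_pasture * sub$area_ha))
    expect_equal(row$area_forest, sum(sub$cover_forest * sub$area_ha))
  }
  expect_equal(sum(cl$table$n_cells), nrow(cells))
})

test_that("disaggregation is proportional, conservative and closure-safe", {
  w <- fx_world_small()
  cells <- w$cells[w$cells$country_id == "C01", ][1:2, ]
  # zero delta: no change
  expect_equal(disaggregate(cells, c(cover_cereals_c3 = 0)), cells)

  # engineered availability 30/70 ha; +10 ha cropland splits +3/+7
  cells2 <- cells
  cells2$protected_frac <- 0
  cells2$cover_forest <- (c(30, 70) / 2) / cells2$area_ha
  cells2$cover_natural <- (c(30, 70) / 2) / cells2$area_ha
  cov_cols <- grep("^cover_", names(cells2), value = TRUE)
  other <- setdiff(cov_cols, c("cover_forest", "cover_natural",
                               "cover_cereals_c3"))
  cells2$cover_cereals_c3 <- 0
  for (v in other) cells2[[v]] <- 0
  cells2$cover_urban <- 1 - cells2$cover_forest - cells2$cover_natural
  out <- disaggregate(cells2, c(cover_cereals_c3 = 10),
                      min_natural_frac = 0)
  gained <- (out$cover_cereals_c3 - cells2$cover_cereals_c3) * cells2$area_ha
  expect_equal(gained, c(3, 7), tolerance = 1e-9)
  # expansion debited equally from forest and other natural
  expect_equal((cells2$cover_forest - out$cover_forest) * cells2$area_ha,
               gained / 2, tolerance = 1e-9)

  # random deltas conserve cluster totals and closure
  set.seed(12)
  cells3 <- w$cells[w$cells$country_id == "C02", ][1:4, ]
  for (rep in 1:10) {
    d <- c(cover_cereals_c3 = runif(1, -50, 200),
           cover_pasture = runif(1, -50, 200))
    cur_c3 <- sum(cells3$cover_cereals_c3 * cells3$area_ha)
    d["cover_cereals_c3"] <- max(d["cover_cereals_c3"], -0.9 * cur_c3)
    out <- disaggregate(cells3, d)
    for (cls in names(d)) {
      got <- sum(out[[cls]] * cells3$area_ha) -
        sum(cells3[[cls]] * cells3$area_ha)
      expect_equal(got, unname(d[cls]), tolerance = 1e-9)
    }
    cov <- out[, grep("^cover_", names(out))]
    expect_true(all(abs(rowSums(cov) - 1) < 1e-9))
    expect_true(all(cov >= -1e-12))
  }

  # infeasible expansion names the problem
  expect_error(disaggregate(cells2, c(cover_cereals_c3 = 1e9),
                            min_natural_frac = 0), "infeasible expansion")
})
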