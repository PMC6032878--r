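#' Cluster a country's grid cells for tractable optimisation
#'
#' Groups similar (not necessarily contiguous) cells within one country by
#' k-means on standardised features: per-crop rain-fed and irrigated yield
#' anchors at 200 kgN/ha plus land-cover fractions.  Features are z-scored
#' within the country (yields and fractions live on different scales);
#' zero-variance features are dropped.  Deterministic given the seed.
#'
#' @param world an `agro_world`.
#' @param country_id the country to cluster.
#' @param k number of clusters, `1 <= k <=` number of cells; defaults to
#'   [choose_k()].
#' @param seed integer seed for centroid initialisation.
#' @return data.frame (`cell_id`, `cluster_id`) with cluster ids of the form
#'   `<country>_k<j>`.
#' @export
cluster_country <- function(world, country_id, k = NULL, seed = 1) {
  cells <- world$cells[world$cells$country_id == country_id, ]
  if (!nrow(cells)) stop("unknown country ", country_id, call. = FALSE)
  if (is.null(k)) k <- choose_k(world, country_id)
  if (k < 1 || k > nrow(cells))
    stop("k must be in 1..", nrow(cells), " for ", country_id, call. = FALSE)
  feats <- cluster_features(world, cells)
  # canonical cell order so results do not depend on input row order
  ord <- order(cells$cell_id)
  cells <- cells[ord, ]; feats <- feats[ord, , drop = FALSE]
  if (k == 1 || ncol(feats) == 0) {
    assign <- rep(1L, nrow(cells))
  } else if (k == nrow(cells)) {
    assign <- seq_len(nrow(cells))
  } else {
    set.seed(as.integer(seed))
    km <- kmeans(feats, centers = k, nstart = 25, iter.max = 100)
    assign <- km$cluster
  }
  data.frame(cell_id = cells$cell_id,
             cluster_id = sprintf("%s_k%d", country_id, assign))
}

cluster_features <- function(world, cells) {
  an <- world$anchors[world$anchors$cell_id %in% cells$cell_id, ]
  f <- cells[, grep("^cover_", names(cells)), drop = FALSE]
  for (cr in world$crops) {
    sub <- an[an$crop == cr, ]
    i <- match(cells$cell_id, sub$cell_id)
    f[[paste0("y200rf_", cr)]] <- sub$y_n200_rf[i]
    f[[paste0("y200ir_", cr)]] <- sub$y_n200_ir[i]
  }
  f <- as.matrix(f)
  v <- apply(f, 2, sd)
  f <- f[, v > 1e-12, drop = FALSE]
  if (ncol(f)) scale(f) else f
}

#' Choose the number of clusters for a country
#'
#' Heuristic rising with country size and heterogeneity:
#' `k = ceil(w sqrt(n) (1 + cv))` clamped to `[1, n]`, where `cv` is the mean
#' coefficient of variation of the clustering features; a perfectly
#' homogeneous country collapses to a single cluster.
#'
#' @param world an `agro_world`.
#' @param country_id country.
#' @param weight scale factor `w` (default 0.5).
#' @return integer number of clusters.
#' @export
choose_k <- function(world, country_id, weight = 0.5) {
  cells <- world$cells[world$cells$country_id == country_id, ]
  if (!nrow(cells)) stop("unknown country ", country_id, call. = FALSE)
  n <- nrow(cells)
  if (n == 1) return(1L)
  an <- world$anchors[world$anchors$cell_id %in% cells$cell_id, ]
  cvs <- vapply(split(an$y_n200_rf, an$crop),
                function(y) if (mean(y) > 0) sd(y) / mean(y) else 0, 0)
  cv <- mean(cvs)
  if (cv < 1e-9) return(1L)    # homogeneous country: one cluster
  max(1L, min(n, as.integer(ceiling(weight * sqrt(n) * (1 + cv)))))
}

#' Aggregate cells into cluster records
#'
#' Computes per-cluster land-cover areas (ha), area-weighted mean yield
#' anchors per crop, pasture yield, irrigation requirement, available
#' irrigation water and available natural (convertible) area.  Aggregate
#' areas equal the sum over members exactly.
#'
#' @param world an `agro_world`.
#' @param membership data.frame (`cell_id`, `cluster_id`) from
#'   [cluster_country()] (possibly several countries' rows bound together).
#' @param water optional [build_water_budget()] result giving per-cell
#'   available water; defaults to zero availability.
#' @param min_natural_frac minimum fraction of each cell kept under forest
#'   or other natural cover when computing convertible area.
#' @return list of class `agro_clusters`: `membership`, `table` (one row per
#'   cluster), `anchors` (cluster-level anchor table usable with
#'   [fit_yield_surface()]).
#' @export
aggregate_clusters <- function(world, membership, water = NULL,
                               min_natural_frac = 0.05) {
  cells <- world$cells[match(membership$cell_id, world$cells$cell_id), ]
  if (anyNA(cells$cell_id)) stop("membership references unknown cells")
  cells$cluster_id <- membership$cluster_id
  cov_cols <- grep("^cover_", names(cells), value = TRUE)
  avail_w <- if (is.null(water)) rep(0, nrow(cells)) else
    water$cell_available_km3[match(cells$cell_id, water$cell_id)]

  rows <- lapply(split(cells, cells$cluster_id), function(d) {
    out <- data.frame(cluster_id = d$cluster_id[1],
                      country_id = d$country_id[1],
                      n_cells = nrow(d), area_ha = sum(d$area_ha))
    for (cc in cov_cols)
      out[[sub("^cover_", "area_", cc)]] <- sum(d[[cc]] * d$area_ha)
    nat <- d$cover_forest + d$cover_natural
    reserve <- pmax(d$protected_frac, min_natural_frac)
    out$avail_natural_ha <- sum(pmax(0, nat - reserve) * d$area_ha)
    out$forest_ha <- sum(d$cover_forest * d$area_ha)
    out$pasture_yield <- weighted.mean(d$pasture_yield, d$area_ha)
    out$water_km3 <- sum(avail_w[match(d$cell_id, cells$cell_id)])
    out$aridity <- weighted.mean(d$aridity, d$area_ha)
    out
  })
  tab <- do.call(rbind, rows); rownames(tab) <- NULL

  an <- world$anchors[world$anchors$cell_id %in% cells$cell_id, ]
  an$cluster_id <- cells$cluster_id[match(an$cell_id, cells$cell_id)]
  an$w <- cells$area_ha[match(an$cell_id, cells$cell_id)]
  agg <- do.call(rbind, lapply(split(an, list(an$cluster_id, an$crop),
                                     drop = TRUE), function(d) {
    data.frame(cell_id = d$cluster_id[1], crop = d$crop[1],
               y_n0_rf = weighted.mean(d$y_n0_rf, d$w),
               y_n200_rf = weighted.mean(d$y_n200_rf, d$w),
               y_n1000_rf = weighted.mean(d$y_n1000_rf, d$w),
               y_n0_ir = weighted.mean(d$y_n0_ir, d$w),
               y_n200_ir = weighted.mean(d$y_n200_ir, d$w),
               y_n1000_ir = weighted.mean(d$y_n1000_ir, d$w),
               irrig_req_km3_ha = weighted.mean(d$irrig_req_km3_ha, d$w))
  }))
  rownames(agg) <- NULL

  structure(list(membership = membership, table = tab, anchors = agg,
                 min_natural_frac = min_natural_frac),
            class = "agro_clusters")
}

#' Disaggregate cluster-level land-cover changes to member cells
#'
#' Expansion of an agricultural class is distributed over member cells in
#' proportion to their available natural area (unprotected forest plus other
#' natural above the minimum-natural reserve) and debited equally from
#' forest and other natural vegetation while both have headroom; contraction
#' is distributed in proportion to each cell's current area of the shrinking
#' class and credited to other natural vegetation.  Cluster deltas are
#' conserved to 1e-9 and no cell fraction leaves \[0, 1\].
#'
#' @param cells member-cell rows of `world$cells` (one cluster).
#' @param deltas named numeric vector of area changes in ha; names are cover
#'   classes (`cover_<crop>` or `cover_pasture`).
#' @param min_natural_frac minimum natural fraction kept per cell.
#' @return the updated cell rows.
#' @export
disaggregate <- function(cells, deltas, min_natural_frac = 0.05) {
  deltas <- deltas[abs(deltas) > 0]
  if (!length(deltas)) return(cells)
  # contractions first so freed land is available to expansions in the same
  # cluster-level step
  for (cls in names(sort(deltas))) {
    d <- deltas[[cls]]
    if (d < 0) {
      cur <- cells[[cls]] * cells$area_ha
      tot <- sum(cur)
      if (-d > tot + 1e-6)
        stop("infeasible contraction of ", cls, ": ", -d, " > ", tot,
             call. = FALSE)
      take <- if (tot > 0) cur / tot * (-d) else rep(0, nrow(cells))
      cells[[cls]] <- cells[[cls]] - take / cells$area_ha
      cells$cover_natural <- cells$cover_natural + take / cells$area_ha
    } else {
      nat <- cells$cover_forest + cells$cover_natural
      reserve <- pmax(cells$protected_frac, min_natural_frac)
      avail <- pmax(0, nat - reserve) * cells$area_ha
      tot <- sum(avail)
      if (d > tot + 1e-6)
        stop("infeasible expansion of ", cls, " by ", d,
             " ha: only ", tot, " ha of convertible natural land",
             call. = FALSE)
      give <- if (tot > 0) avail / tot * d else rep(0, nrow(cells))
      gf <- give / cells$area_ha
      # equal split forest / other natural, remainder from the deeper pool
      half <- gf / 2
      from_forest <- pmin(half, pmax(0, cells$cover_forest -
                                       reserve * cells$cover_forest /
                                       pmax(nat, 1e-12)))
      from_forest <- pmin(gf, pmax(from_forest, gf - pmax(0, cells$cover_natural)))
      from_forest <- pmin(from_forest, cells$cover_forest)
      from_nat <- gf - from_forest
      cells$cover_forest <- cells$cover_forest - from_forest
      cells$cover_natural <- cells$cover_natural - from_nat
      cells[[cls]] <- cells[[cls]] + gf
    }
  }
  cov_cols <- grep("^cover_", names(cells), value = TRUE)
  if (any(abs(rowSums(cells[, cov_cols]) - 1) > 1e-9))
    stop("internal error: closure lost in disaggregation")
  if (any(cells[, cov_cols] < -1e-9))
    stop("internal error: negative cover after disaggregation")
  for (cc in cov_cols) cells[[cc]] <- pmax(cells[[cc]], 0)
  cells
}
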