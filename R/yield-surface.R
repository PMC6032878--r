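#' Fit continuous yield-response surfaces to factorial anchors
#'
#' For every cell-by-crop anchor set, fits a saturating-exponential response
#' to fertiliser separately for the rain-fed and irrigated regimes,
#' `y(F) = y0 + (y_inf - y0) (1 - exp(-k_F F))`, passing exactly through the
#' three anchors at F = 0, 200 and 1000 kgN/ha.  Irrigation enters as a
#' concave blend between the two regimes and management as a concave
#' multiplier reaching 1 (the anchor maximum) at full intensity.  Annual
#' exogenous technology change scales yields multiplicatively.
#'
#' @param anchors anchor table as produced by [generate_world()] (`$anchors`);
#'   columns `cell_id`, `crop`, `y_n0_rf`, `y_n200_rf`, `y_n1000_rf`,
#'   `y_n0_ir`, `y_n200_ir`, `y_n1000_ir`, `irrig_req_km3_ha`.
#' @param calibration calibration factor applied to all yields (see
#'   [calibrate_factor()]); scalar or named per-crop vector.
#' @param k_I irrigation blend shape (> 0); larger values mean most of the
#'   irrigation response arrives at low irrigation fractions.
#' @param g0 management floor in (0, 1]: the yield multiplier at zero
#'   management intensity.
#' @param k_M management response shape (> 0).
#' @param tech_rate exogenous annual yield increment (fraction per year);
#'   the central value is 0.002.
#' @param base_year calendar year at which surfaces reproduce the anchors.
#' @return object of class `yield_surface`: a data.frame of per-(cell, crop)
#'   parameters with the shape constants and calibration in attributes.
#' @examples
#' w <- generate_world(1, 4, n_crops = 2, seed = 1)
#' s <- fit_yield_surface(w$anchors)
#' evaluate_yield(s, w$anchors$cell_id[1], w$anchors$crop[1],
#'                fert = 200, irr_frac = 0, mgmt = 1)
#' @export
fit_yield_surface <- function(anchors, calibration = 1.0, k_I = 2.0,
                              g0 = 0.5, k_M = 2.0, tech_rate = 0.002,
                              base_year = AGROSIM_BASE_YEAR) {
  stopifnot(k_I > 0, g0 > 0, g0 <= 1, k_M > 0, all(calibration > 0))
  need <- c("cell_id", "crop", "y_n0_rf", "y_n200_rf", "y_n1000_rf",
            "y_n0_ir", "y_n200_ir", "y_n1000_ir", "irrig_req_km3_ha")
  if (!all(need %in% names(anchors)))
    stop("anchors missing columns: ",
         paste(setdiff(need, names(anchors)), collapse = ", "), call. = FALSE)

  bad <- !(anchors$y_n200_rf >= anchors$y_n0_rf - 1e-9 &
           anchors$y_n1000_rf >= anchors$y_n200_rf - 1e-9 &
           anchors$y_n200_ir >= anchors$y_n0_ir - 1e-9 &
           anchors$y_n1000_ir >= anchors$y_n200_ir - 1e-9)
  if (any(bad))
    stop("anchor monotonicity violated at ",
         paste(head(paste0(anchors$cell_id[bad], "/", anchors$crop[bad]), 5),
               collapse = ", "), call. = FALSE)

  fit_regime <- function(y0, y200, y1000) {
    n <- length(y0)
    k <- numeric(n); yinf <- y0
    for (i in seq_len(n)) {
      p <- fit_exp_through_anchors(y0[i], y200[i], y1000[i])
      k[i] <- p[1]; yinf[i] <- p[2]
    }
    list(k = k, yinf = yinf)
  }
  rf <- fit_regime(anchors$y_n0_rf, anchors$y_n200_rf, anchors$y_n1000_rf)
  ir <- fit_regime(anchors$y_n0_ir, anchors$y_n200_ir, anchors$y_n1000_ir)

  calib <- if (length(calibration) == 1) rep(calibration, nrow(anchors))
           else unname(calibration[anchors$crop])
  if (anyNA(calib)) stop("per-crop calibration missing some crops")

  params <- data.frame(
    cell_id = anchors$cell_id, crop = anchors$crop,
    y0_rf = anchors$y_n0_rf, yinf_rf = rf$yinf, k_rf = rf$k,
    y0_ir = anchors$y_n0_ir, yinf_ir = ir$yinf, k_ir = ir$k,
    irrig_req_km3_ha = anchors$irrig_req_km3_ha,
    calibration = calib
  )
  structure(params, class = c("yield_surface", "data.frame"),
            k_I = k_I, g0 = g0, k_M = k_M, tech_rate = tech_rate,
            base_year = base_year)
}

# Solve (y200 - y0)/(y1000 - y0) = (1 - e^{-200k})/(1 - e^{-1000k}) for k,
# then y_inf = y0 + (y1000 - y0)/(1 - e^{-1000k}).  The ratio is increasing
# in k from 0.2 (k -> 0, linear response) to 1 (k -> Inf); flat anchors give
# k = 0 by convention, near-linear anchors a tiny k.
fit_exp_through_anchors <- function(y0, y200, y1000, tol = 1e-12) {
  if (y1000 <= y0 + 1e-9) return(c(0, y0))          # flat response
  if (y200 > y1000) y200 <- y1000                    # clamp noisy middle
  r <- (y200 - y0) / (y1000 - y0)
  ratio <- function(k) (1 - exp(-200 * k)) / (1 - exp(-1000 * k))
  if (r <= 0.2 + 1e-12) {          # convex or linear: smallest representable k
    k <- 1e-8
  } else if (r >= ratio(1)) {
    k <- 1                          # effectively saturated by F = 200
  } else {
    k <- uniroot(function(k) ratio(k) - r, c(1e-8, 1), tol = tol)$root
  }
  yinf <- y0 + (y1000 - y0) / (1 - exp(-1000 * k))
  c(k, yinf)
}

surface_attrs <- function(surface) {
  list(k_I = attr(surface, "k_I"), g0 = attr(surface, "g0"),
       k_M = attr(surface, "k_M"), tech_rate = attr(surface, "tech_rate"),
       base_year = attr(surface, "base_year"))
}

#' Evaluate a yield surface
#'
#' Returns calibrated yield (t/ha) at the given fertiliser rate, irrigation
#' fraction of the full requirement, management intensity and year:
#' `calibration * g(m) * [y_rf(F) + (y_ir(F) - y_rf(F)) w(x)] *
#' (1 + tech_rate)^(year - base_year)` with `w` and `g` concave,
#' `w(0) = 0`, `w(1) = 1`, `g(1) = 1`.
#'
#' @param surface a `yield_surface`.
#' @param cell_id,crop vectors identifying the (cell, crop) rows; recycled
#'   against the input vectors.
#' @param fert fertiliser rate, kgN/ha, >= 0.
#' @param irr_frac irrigation as a fraction of the full requirement, in
#'   \[0, 1\].
#' @param mgmt management intensity in \[0, 1\]; 1 attains the anchor yields.
#' @param year calendar year (technology scaling).
#' @return numeric vector of yields, t/ha.
#' @export
evaluate_yield <- function(surface, cell_id, crop, fert, irr_frac = 0,
                           mgmt = 1, year = NULL) {
  stopifnot(inherits(surface, "yield_surface"))
  at <- surface_attrs(surface)
  if (is.null(year)) year <- at$base_year
  if (any(fert < 0) || any(irr_frac < -1e-12) || any(irr_frac > 1 + 1e-12) ||
      any(mgmt < -1e-12) || any(mgmt > 1 + 1e-12))
    stop("inputs out of range: fert >= 0, irr_frac and mgmt in [0,1]",
         call. = FALSE)
  key <- paste(cell_id, crop, sep = "\r")
  skey <- paste(surface$cell_id, surface$crop, sep = "\r")
  i <- match(key, skey)
  if (anyNA(i))
    stop("unknown cell/crop: ", paste(head(key[is.na(i)]), collapse = ", "),
         call. = FALSE)
  y_rf <- surface$y0_rf[i] +
    (surface$yinf_rf[i] - surface$y0_rf[i]) * (1 - exp(-surface$k_rf[i] * fert))
  y_ir <- surface$y0_ir[i] +
    (surface$yinf_ir[i] - surface$y0_ir[i]) * (1 - exp(-surface$k_ir[i] * fert))
  w <- (1 - exp(-at$k_I * pmin(pmax(irr_frac, 0), 1))) / (1 - exp(-at$k_I))
  g <- at$g0 + (1 - at$g0) *
    (1 - exp(-at$k_M * pmin(pmax(mgmt, 0), 1))) / (1 - exp(-at$k_M))
  pmax(0, surface$calibration[i] * g * (y_rf + (y_ir - y_rf) * w) *
         (1 + at$tech_rate)^(year - at$base_year))
}

#' Calibration factor by slope-only regression
#'
#' Least-squares slope through the origin of observed on simulated yields,
#' optionally weighted (e.g. by harvested area or production):
#' `c = sum(w s o) / sum(w s^2)`.  Used to translate simulated potential
#' yields into observed-yield units per crop type.
#'
#' @param simulated,observed per-unit-area yields (t/ha), same length.
#' @param weights non-negative weights, defaults to equal.
#' @return the scalar calibration factor.
#' @examples
#' calibrate_factor(c(2, 4), c(1, 2))  # 0.5
#' @export
calibrate_factor <- function(simulated, observed, weights = NULL) {
  stopifnot(length(simulated) == length(observed))
  if (is.null(weights)) weights <- rep(1, length(simulated))
  stopifnot(length(weights) == length(simulated), all(weights >= 0))
  keep <- is.finite(simulated) & is.finite(observed) & weights > 0
  s <- simulated[keep]; o <- observed[keep]; w <- weights[keep]
  if (!length(s) || all(s == 0))
    stop("degenerate data: no pair with simulated > 0", call. = FALSE)
  sum(w * s * o) / sum(w * s^2)
}

#' @export
print.yield_surface <- function(x, ...) {
  at <- surface_attrs(x)
  cat("Yield surfaces:", nrow(x), "cell-crop combinations\n")
  cat(sprintf("  shapes: k_I=%.3g, g0=%.3g, k_M=%.3g; tech %.2f%%/yr; base year %d\n",
              at$k_I, at$g0, at$k_M, 100 * at$tech_rate, at$base_year))
  cat(sprintf("  rain-fed asymptote range: %.2f-%.2f t/ha\n",
              min(x$yinf_rf), max(x$yinf_rf)))
  invisible(x)
}

#' Plot a fitted yield-response surface
#'
#' Draws yield against fertiliser rate at several irrigation fractions for
#' one cell and crop (full management, base year) — the standard picture of
#' diminishing returns to both inputs.
#'
#' @param x a `yield_surface`.
#' @param cell_id,crop the combination to plot (defaults to the first row).
#' @param irr_fracs irrigation fractions to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.yield_surface <- function(x, cell_id = NULL, crop = NULL,
                               irr_fracs = c(0, 0.5, 1), ...) {
  if (is.null(cell_id)) cell_id <- x$cell_id[1]
  if (is.null(crop)) crop <- x$crop[x$cell_id == cell_id][1]
  fert <- seq(0, 1000, by = 10)
  ym <- sapply(irr_fracs, function(ir)
    evaluate_yield(x, rep(cell_id, length(fert)), rep(crop, length(fert)),
                   fert, ir, 1))
  graphics::matplot(fert, ym, type = "l", lty = 1,
                    xlab = "fertiliser (kgN/ha)", ylab = "yield (t/ha)",
                    main = paste(crop, "at", cell_id), ...)
  graphics::legend("bottomright", legend = paste0("irr=", irr_fracs),
                   lty = 1, col = seq_along(irr_fracs), bty = "n")
  invisible(x)
}
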