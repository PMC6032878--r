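make_anchor_row <- function(y0, y200, y1000, gain = 1.3,
                            cell = "x", crop = "cereals_c3") {
  data.frame(cell_id = cell, crop = crop,
             y_n0_rf = y0, y_n200_rf = y200, y_n1000_rf = y1000,
             y_n0_ir = y0 * gain, y_n200_ir = y200 * gain,
             y_n1000_ir = y1000 * gain, irrig_req_km3_ha = 5e-6)
}

test_that("flat anchors give a constant response with zero rate", {
  s <- fit_yield_surface(make_anchor_row(1, 1, 1))
  expect_equal(s$k_rf, 0)
  expect_equal(s$yinf_rf, 1)
  for (f in c(0, 137, 1000))
    expect_equal(evaluate_yield(s, "x", "cereals_c3", f, 0, 1), 1,
                 tolerance = 1e-12)
})

test_that("fertiliser rate solves the anchor-ratio equation", {
  # independent oracle: bisection on r(k) = (1-e^{-200k})/(1-e^{-1000k})
  y0 <- 2; y200 <- 6; y1000 <- 8
  target <- (y200 - y0) / (y1000 - y0)
  lo <- 1e-9; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    r <- (1 - exp(-200 * mid)) / (1 - exp(-1000 * mid))
    if (r < target) lo <- mid else hi <- mid
  }
  k_oracle <- (lo + hi) / 2

  s <- fit_yield_surface(make_anchor_row(y0, y200, y1000))
  expect_equal(s$k_rf, k_oracle, tolerance = 1e-6)
  # substituting the root back reproduces both anchor equations
  yinf <- s$yinf_rf
  expect_equal(y0 + (yinf - y0) * (1 - exp(-200 * s$k_rf)), y200,
               tolerance = 1e-8)
  expect_equal(y0 + (yinf - y0) * (1 - exp(-1000 * s$k_rf)), y1000,
               tolerance = 1e-8)
})

test_that("surfaces reproduce all six anchors on a generated world", {
  w <- fx_world_small()
  s <- fit_yield_surface(w$anchors)
  an <- w$anchors
  combos <- list(c(0, 0, "y_n0_rf"), c(200, 0, "y_n200_rf"),
                 c(1000, 0, "y_n1000_rf"), c(0, 1, "y_n0_ir"),
                 c(200, 1, "y_n200_ir"), c(1000, 1, "y_n1000_ir"))
  for (cb in combos) {
    y <- evaluate_yield(s, an$cell_id, an$crop, as.numeric(cb[1]),
                        as.numeric(cb[2]), 1)
    expect_equal(y, an[[cb[3]]], tolerance = 1e-6)
  }
})

test_that("yield is monotone and concave along every input axis", {
  w <- fx_world_small()
  s <- fit_yield_surface(w$anchors)
  cell <- w$anchors$cell_id[5]; crop <- w$anchors$crop[5]
  fs <- seq(0, 1000, length.out = 10)
  irs <- seq(0, 1, length.out = 10)
  ms <- seq(0, 1, length.out = 10)
  g <- expand.grid(f = fs, ir = irs, m = ms)
  g$y <- evaluate_yield(s, cell, crop, g$f, g$ir, g$m)
  arr <- array(g$y, dim = c(10, 10, 10))
  for (ax in 1:3) {
    d1 <- apply(arr, setdiff(1:3, ax), diff)
    expect_true(all(d1 >= -1e-9))
    d2 <- apply(arr, setdiff(1:3, ax), function(v) diff(diff(v)))
    expect_true(all(d2 <= 1e-9))
  }
})

test_that("technology change compounds multiplicatively and can be off", {
  a <- make_anchor_row(2, 6, 8)
  s <- fit_yield_surface(a, tech_rate = 0.002)
  y0 <- evaluate_yield(s, "x", "cereals_c3", 150, 0.4, 0.8, year = 2010)
  y10 <- evaluate_yield(s, "x", "cereals_c3", 150, 0.4, 0.8, year = 2020)
  expect_equal(y10 / y0, 1.002^10, tolerance = 1e-12)

  s0 <- fit_yield_surface(a, tech_rate = 0)
  expect_equal(
    evaluate_yield(s0, "x", "cereals_c3", 150, 0.4, 0.8, year = 2050),
    evaluate_yield(s0, "x", "cereals_c3", 150, 0.4, 0.8, year = 2010),
    tolerance = 1e-12)
})

test_that("invalid anchors and out-of-range inputs are rejected", {
  bad <- make_anchor_row(5, 3, 8)   # mid anchor below zero-N anchor
  expect_error(fit_yield_surface(bad), "cereals_c3")
  s <- fit_yield_surface(make_anchor_row(2, 6, 8))
  expect_error(evaluate_yield(s, "x", "cereals_c3", -5, 0, 1), "range")
  expect_error(evaluate_yield(s, "x", "cereals_c3", 0, 1.2, 1), "range")
  expect_error(evaluate_yield(s, "x", "cereals_c3", 0, 0, 2), "range")
  expect_error(evaluate_yield(s, "nope", "cereals_c3", 0, 0, 1), "unknown")
})

test_that("calibration is a weighted slope through the origin", {
  expect_equal(calibrate_factor(c(2, 4, 6), c(2, 4, 6)), 1.0)
  expect_equal(calibrate_factor(c(2, 4, 6), c(1, 2, 3), c(5, 1, 2)), 0.5)

  set.seed(99)
  s <- runif(20, 1, 10); o <- 0.8 * s + rnorm(20, 0, 0.3)
  w <- runif(20, 0.5, 2)
  # oracle: generic weighted least squares with the intercept fixed at zero
  # via the normal equations on the single-column design matrix
  beta <- solve(t(s * w) %*% s, t(s * w) %*% o)[1, 1]
  expect_equal(calibrate_factor(s, o, w), beta, tolerance = 1e-12)
  # linearity: scaling observations scales the factor
  expect_equal(calibrate_factor(s, 3 * o, w), 3 * beta, tolerance = 1e-12)
  expect_error(calibrate_factor(c(0, 0), c(1, 1)), "degenerate")
})

test_that("calibration scales evaluated yields uniformly", {
  a <- make_anchor_row(2, 6, 8)
  s1 <- fit_yield_surface(a, calibration = 1)
  s2 <- fit_yield_surface(a, calibration = 0.7)
  expect_equal(evaluate_yield(s2, "x", "cereals_c3", 200, 0.5, 0.9),
               0.7 * evaluate_yield(s1, "x", "cereals_c3", 200, 0.5, 0.9),
               tolerance = 1e-12)
})
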