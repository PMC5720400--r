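test_that("closed-band sampling reproduces constant and linear fields exactly", {
  g <- bench_geometry()
  m <- build_mask(msc_spec(20), g, "A")
  cc <- detector_coords(g)
  # constant scatter under the closed bands
  img_c <- matrix(0.7, g$n_u, g$n_v)
  s <- sample_closed_scatter(img_c, m, g)
  expect_true(all(s$values == 0.7))
  est <- interpolate_scatter(s, g)
  expect_equal(est, matrix(0.7, g$n_u, g$n_v), tolerance = 1e-12)
  # linear plane a*v + b: band means sit on the line at the band centres
  img_l <- matrix(rep(0.002 * cc$v + 1, each = g$n_u), g$n_u, g$n_v)
  sl <- sample_closed_scatter(img_l, m, g, spacing = 1000)  # one sample per band
  expect_equal(as.numeric(sl$values[1, ]), 0.002 * sl$v + 1, tolerance = 1e-12)
  est_l <- interpolate_scatter(sl, g, method = "linear")
  expect_equal(est_l, img_l, tolerance = 1e-9)
})

test_that("fewer than two closed bands is an error", {
  g <- bench_geometry()
  img <- matrix(1, g$n_u, g$n_v)
  one_band <- manual_mask(g,
    open_bands = data.frame(v_lo = -150, v_hi = 0),
    closed_bands = data.frame(v_lo = 0, v_hi = 150))
  expect_error(sample_closed_scatter(img, one_band, g), "insufficient")
  # a slit wide enough to open the whole detector leaves no closed band at all
  gt <- tiny_geometry()
  all_open <- build_mask(msc_spec(500), gt, "A")
  expect_error(sample_closed_scatter(matrix(1, gt$n_u, gt$n_v), all_open, gt),
               "insufficient")
})

test_that("subtraction clips at zero and zeroes closed bands", {
  g <- tiny_geometry()
  m <- build_mask(msc_spec(30), g, "A")
  img <- matrix(1, g$n_u, g$n_v)
  # zero estimate: output equals the open-band image
  r0 <- subtract_scatter(img, matrix(0, g$n_u, g$n_v), m, g)
  expect_equal(r0$values, m$values)
  expect_equal(r0$n_clipped, 0)
  # over-estimate: everything clips to zero and is counted
  r2 <- subtract_scatter(img, matrix(2, g$n_u, g$n_v), m, g)
  expect_true(all(r2$values == 0))
  expect_equal(r2$n_clipped, sum(m$values == 1))
})

test_that("an exact scatter estimate recovers the masked primary", {
  g <- bench_geometry()
  ph <- build_simple_phantom()
  params <- scatter_params()
  pair <- acquire(ph, g, msc_spec(10), params, angles = 0)
  truth_a <- pair$truth$scatter_a$values[, , 1]
  half <- subtract_scatter(pair$stack_a$values[, , 1], truth_a, pair$masks$A, g)
  masked_primary <- pair$masks$A$values * pair$truth$primary$values[, , 1]
  expect_equal(half$values, masked_primary, tolerance = 1e-12)
})

test_that("merging a zero-scatter pair restores the unmasked primary exactly", {
  g <- bench_geometry()
  ph <- build_simple_phantom()
  for (w in c(10, 30)) {
    pair <- acquire(ph, g, msc_spec(w), scatter_params(spr = 0), angles = 0)
    corr <- correct_stack(pair)
    expect_equal(corr$stack$values[, , 1], pair$truth$primary$values[, , 1],
                 tolerance = 1e-12)
    expect_equal(sum(corr$n_clipped), 0)
  }
})

test_that("merge rejects mismatched view angles", {
  g <- tiny_geometry()
  m <- list(A = build_mask(msc_spec(30), g, "A"),
            B = build_mask(msc_spec(30), g, "B"))
  z <- matrix(0, g$n_u, g$n_v)
  expect_error(merge_pair(z, z, m, angle_a = 0, angle_b = 1), "mismatch")
  # an empty half-B passes half-A through unchanged under ideal masks
  expect_equal(merge_pair(z + 1, z, m), z + 1)
})

test_that("the correction never increases any pixel of the raw merge", {
  g <- bench_geometry()
  ph <- build_lung_bone_phantom()
  pair <- acquire(ph, g, msc_spec(20), scatter_params(), angles = 0)
  corr <- correct_stack(pair)
  raw_merge <- merge_pair(pair$stack_a$values[, , 1], pair$stack_b$values[, , 1],
                          pair$masks)
  expect_true(all(corr$stack$values[, , 1] <= raw_merge + 1e-12))
})

test_that("linear interpolation error scales as the square of the band pitch", {
  g <- bench_geometry()
  cc <- detector_coords(g)
  # smooth synthetic scatter field with bounded curvature along v
  truth <- matrix(rep(1 + 0.5 * exp(-cc$v^2 / (2 * 60^2)), each = g$n_u),
                  g$n_u, g$n_v)
  err_for_width <- function(w) {
    m <- build_mask(msc_spec(w), g, "A")
    s <- sample_closed_scatter(truth, m, g, spacing = 1000)  # band centres only
    est <- interpolate_scatter(s, g, method = "linear")
    span <- abs(cc$v) < 100    # interior, away from extrapolated margins
    max(abs(est[1, span] - truth[1, span]))
  }
  e20 <- err_for_width(20)
  e10 <- err_for_width(10)
  expect_gt(e20 / e10, 3.2)   # halving the pitch cuts the error ~4x
})

test_that("the estimate tracks blurred-primary scatter within 5 percent", {
  g <- bench_geometry()
  ph <- build_simple_phantom()
  params <- scatter_params()
  sc <- calibrate_scatter_scale(ph, g, params)
  pr <- project_primary(ph, g, 0)$primary
  truth <- simulate_scatter(pr, g, params, sc)   # smooth unmasked field
  m <- build_mask(msc_spec(10), g, "A")          # 15 mm band pitch on the detector
  s <- sample_closed_scatter(truth, m, g)
  est <- interpolate_scatter(s, g)
  expect_lt(max(abs(est - truth)) / max(truth), 0.05)
})

test_that("correcting a full small orbit is deterministic and self-consistent", {
  g <- tiny_geometry(n_u = 48L, n_v = 48L, n_views = 6L)
  ph <- uniform_cyl()
  pair <- acquire(ph, g, msc_spec(30), scatter_params())
  c1 <- correct_stack(pair)
  c2 <- correct_stack(pair)
  expect_identical(c1$stack$values, c2$stack$values)
  expect_true(all(c1$residual < 0.05))
})
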