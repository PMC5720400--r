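test_that("log normalization converts intensities to line integrals", {
  st <- projection_stack(array(c(1, exp(-2), 0), c(3, 1, 1)), 0,
                         "total_intensity", i0 = 1)
  p <- log_normalize(st, floor_frac = 1e-6)
  expect_equal(p$values[1, 1, 1], 0)
  expect_equal(p$values[2, 1, 1], 2)
  expect_equal(p$values[3, 1, 1], -log(1e-6))   # floored, finite
  expect_true(all(is.finite(p$values)))
  expect_error(log_normalize(st, i0 = 0), "i0")
  st$values[1] <- -1
  expect_error(log_normalize(st), "non-negative")
})

test_that("FDK is linear and maps zero projections to a zero volume", {
  g <- cone_beam_geometry(n_u = 32L, n_v = 32L, n_views = 24L)
  ph <- uniform_cyl(radius = 60, mu = 0.2)
  ang <- view_angles(g)
  arr <- array(0, c(32, 32, 24))
  for (k in seq_along(ang))
    arr[, , k] <- project_primary(ph, g, ang[k])$line_integral
  grid <- recon_grid(16, 16, 8, 6)
  v0 <- fdk_reconstruct(projection_stack(array(0, dim(arr)), ang, "line_integral"),
                        g, grid)
  expect_true(all(v0$values == 0))
  v1 <- fdk_reconstruct(projection_stack(arr, ang, "line_integral"), g, grid)
  v3 <- fdk_reconstruct(projection_stack(3 * arr, ang, "line_integral"), g, grid)
  expect_equal(v3$values, 3 * v1$values, tolerance = 1e-12)
})

test_that("FDK rejects unsupported orbits", {
  g <- tiny_geometry()
  arr <- array(0, c(g$n_u, g$n_v, 3))
  expect_error(fdk_reconstruct(projection_stack(arr, c(0, 10, 30), "line_integral"),
                               g, recon_grid(8, 8, 8, 4)), "uniform")
  expect_error(fdk_reconstruct(projection_stack(arr, c(0, 60, 120), "line_integral"),
                               g, recon_grid(8, 8, 8, 4)), "360")
})

test_that("a uniform cylinder reconstructs to its attenuation coefficient", {
  g <- cone_beam_geometry(n_u = 64L, n_v = 64L, n_views = 120L)
  ph <- uniform_cyl(radius = 50, mu = 0.2, half_len = 75)   # 0.02 /mm
  ang <- view_angles(g)
  arr <- array(0, c(64, 64, 120))
  for (k in seq_along(ang))
    arr[, , k] <- project_primary(ph, g, ang[k])$line_integral
  grid <- recon_grid(48, 48, 16, 2)
  vol <- fdk_reconstruct(projection_stack(arr, ang, "line_integral"), g, grid)
  gx <- (seq_len(48) - 24.5) * 2
  roi <- outer(gx^2, gx^2, "+") <= 10^2
  mid <- vol$values[, , 8][roi]
  expect_equal(mean(mid), 0.2, tolerance = 0.03)
  # Hamming apodization smooths but keeps the plateau level
  volh <- fdk_reconstruct(projection_stack(arr, ang, "line_integral"), g, grid,
                          filter = "hamming")
  expect_equal(mean(volh$values[, , 8][roi]), 0.2, tolerance = 0.03)
})

test_that("central profiles reflect slice structure and symmetry", {
  vals <- array(0.7, c(9, 9, 5))
  vol <- structure(list(values = vals, grid = recon_grid(9, 9, 5, 2)),
                   class = "volume")
  p <- central_profile(vol, "x")
  expect_true(all(p$values == 0.7))
  expect_equal(p$pos, -rev(p$pos))
  expect_error(central_profile(vol, "x", slice_index = 9), "out of range")
})
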