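test_that("detector coordinates are centred and symmetric", {
  g <- bench_geometry()
  expect_equal(g$pitch_u, 300 / 128)
  cc <- detector_coords(g)
  expect_equal(cc$u[1], -150 + 0.5 * g$pitch_u)
  expect_equal(cc$u, -rev(cc$u))
  expect_equal(cc$v, -rev(cc$v))
  # single-column detector sits at u = 0
  g1 <- cone_beam_geometry(n_u = 1L, det_size_u = 10)
  expect_equal(detector_coords(g1)$u, 0)
})

test_that("geometry validation rejects bad layouts", {
  expect_error(cone_beam_geometry(sad = -1), "sad")
  expect_error(cone_beam_geometry(sad = 1000, sdd = 900), "sdd")
  expect_error(cone_beam_geometry(n_views = 0), "n_views")
  expect_error(msc_spec(0), "slit_width_iso")
  expect_error(msc_spec(10, pitch_ratio = 0), "pitch_ratio")
})

test_that("septa boundaries follow the equi-angular track projection", {
  g <- bench_geometry()
  b <- septa_boundaries(msc_spec(10), g, "A")
  open0 <- b[b$open & b$v_lo < 0 & b$v_hi > 0, ]
  # w = 10 mm at SAD 1000 mm: central open band spans |v| <= 7.5 mm
  expect_equal(open0$v_lo, -7.5, tolerance = 1e-12)
  expect_equal(open0$v_hi, 7.5, tolerance = 1e-12)
  # next edge at sdd * tan(3 * atan(0.005)) = 22.50150 mm (direct evaluation)
  nxt <- sort(b$v_hi[b$v_hi > 7.6])[1]
  expect_equal(nxt, 22.5015001125, tolerance = 1e-9)
  # edges strictly increasing and symmetric about v = 0
  expect_true(all(diff(b$v_lo) > 0))
  expect_equal(sort(b$v_lo), sort(-b$v_hi), tolerance = 1e-9)
})

test_that("phase B is phase A shifted by one septum interval", {
  g <- bench_geometry()
  m <- msc_spec(20)
  ba <- septa_boundaries(m, g, "A")
  bb <- septa_boundaries(m, g, "B")
  beta <- atan(10 / 1000)
  # compare shifted angular edges on the overlapping range
  ea <- sort(ba$theta_lo) + 2 * beta
  eb <- sort(bb$theta_lo)
  common <- intersect(round(ea, 9), round(eb, 9))
  expect_gt(length(common), 5)
})

test_that("ideal complementary masks partition the detector exactly", {
  g <- bench_geometry()
  for (w in c(10, 20, 30)) {
    ma <- build_mask(msc_spec(w), g, "A")
    mb <- build_mask(msc_spec(w), g, "B")
    expect_true(all(ma$values %in% c(0, 1)))
    expect_identical(ma$values + mb$values, matrix(1, g$n_u, g$n_v))
    # mask is constant along u
    expect_equal(ma$values, ma$values[rep(1, g$n_u), ])
  }
})

test_that("phase A open fraction is one half up to band pixel quantization", {
  g <- bench_geometry()
  for (w in c(10, 20, 30)) {
    ma <- build_mask(msc_spec(w), g, "A")
    n_bands <- nrow(ma$open_bands) + nrow(ma$closed_bands)
    expect_lt(abs(mean(ma$values) - 0.5), n_bands / g$n_v)
  }
})

test_that("a slit covering the whole detector gives an all-open mask", {
  g <- tiny_geometry()
  ma <- build_mask(msc_spec(500), g, "A")
  expect_true(all(ma$values == 1))
})

test_that("soft edges give a smooth mask that still sums to one across phases", {
  g <- bench_geometry()
  m <- msc_spec(20, soft_edge_sigma = 2)
  ma <- build_mask(m, g, "A")
  mb <- build_mask(m, g, "B")
  expect_true(all(ma$values >= 0 & ma$values <= 1))
  expect_true(any(ma$values > 0 & ma$values < 1))
  expect_equal(ma$values + mb$values, matrix(1, g$n_u, g$n_v), tolerance = 1e-6)
})

test_that("masks are independent of gantry angle by construction", {
  # the mask API takes no angle: the same mask applies to every view of the
  # acquisition, so stack A's closed bands are identical across views
  g <- tiny_geometry(n_views = 4L)
  pair <- acquire(uniform_cyl(), g, msc_spec(30), scatter_params(spr = 0),
                  reference = FALSE, keep_truth = FALSE)
  closed <- pair$masks$A$values == 0
  for (k in seq_len(4)) expect_true(all(pair$stack_a$values[, , k][closed] == 0))
})
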