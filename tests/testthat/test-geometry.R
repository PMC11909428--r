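test_that("resampling a volume onto its own grid is the identity", {
  ph <- small_phantom(severity = 5, seed = 41)
  out <- resample_volume(ph$volume, ph$volume$grid)
  expect_identical(out$intensities, ph$volume$intensities)
})

test_that("constant volumes stay constant under any resampling", {
  g1 <- grid_spec(16, 20, 4, 10, 20, 100)
  g2 <- grid_spec(9, 13, 3, 16, 30, 120)
  v <- oct_volume(array(77L, c(16, 20, 4)), g1)
  out <- resample_volume(v, g2)
  expect_true(all(out$intensities == 77L))
})

test_that("trilinear resampling evaluates a linear ramp exactly", {
  # axial ramp value = 2 * physical_depth / dz_src, downsampled 2x
  n <- 64
  g1 <- grid_spec(n, 4, 2, 2, 10, 10)
  g2 <- grid_spec(n / 2, 4, 2, 4, 10, 10)
  ramp <- array(rep(2 * seq_len(n) - 2, 4 * 2), c(n, 4, 2))
  v <- oct_volume(ramp, g1)
  out <- resample_volume(v, g2)
  # target centre j (1-based) sits at source index 2j - 0.5; interior samples
  # interpolate the ramp exactly, then round to integer
  j <- 2:(n / 2 - 1)
  expected <- round(2 * (2 * j - 0.5) - 2)
  expect_equal(out$intensities[j, 1, 1], expected)
})

test_that("surface resampling is exact on planes and handles NA footprints", {
  g1 <- grid_spec(64, 24, 8, 10, 20, 100)
  # identical grids: identical map
  m <- matrix(rnorm(8 * 24, mean = 30), 8, 24)
  expect_identical(resample_surface(m, g1, g1), m)
  # flat surface at a fixed physical depth lands at depth/dz rows
  g2 <- grid_spec(128, 24, 8, 5, 20, 100)  # same extents, finer axially
  flat <- matrix(40, 8, 24)  # 40 rows at 10 um = 395 um centre depth
  out <- resample_surface(flat, g1, g2)
  expect_equal(max(abs(out - ((40 - 0.5) * 10 / 5 + 0.5))), 0)
  # tilted plane reproduced exactly at target lateral centres (same extents)
  g3 <- grid_spec(64, 48, 16, 10, 10, 50)
  u1 <- ((seq_len(24) - 0.5) - 12) * 20
  v1 <- ((seq_len(8) - 0.5) - 4) * 100
  plane <- outer(v1, u1, function(v, u) 30 + 0.01 * u + 0.002 * v)
  u3 <- ((seq_len(48) - 0.5) - 24) * 10
  v3 <- ((seq_len(16) - 0.5) - 8) * 50
  expected <- outer(v3, u3, function(v, u) 30 + 0.01 * u + 0.002 * v)
  got <- resample_surface(plane, g1, g3)
  interior <- 2:15
  expect_equal(got[interior, 2:47], expected[interior, 2:47], tolerance = 1e-10)
  # a fully undefined source yields a fully undefined target
  nas <- matrix(NA_real_, 8, 24)
  expect_true(all(is.na(resample_surface(nas, g1, g3))))
})

test_that("volume resampling requires overlapping fields of view", {
  g1 <- grid_spec(8, 8, 2, 10, 10, 10)
  v <- oct_volume(array(1L, c(8, 8, 2)), g1)
  # centre-aligned grids always overlap; the failure surfaces via common_fov
  expect_error(common_fov(g1, g1, offset_mm = c(5, 0)), "overlap")
  expect_s3_class(resample_volume(v, grid_spec(4, 4, 2, 20, 20, 10)),
                  "oct_volume")
})
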