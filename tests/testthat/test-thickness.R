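test_that("thickness maps follow surface and mask modes", {
  g <- grid_spec(60, 8, 4, 3.87, 11.7, 58.7)
  rpe <- matrix(30, 4, 8); bm <- rpe
  s <- oct_surfaces(rpe - 20, rpe, bm, g)
  tm <- rpedc_thickness_map(s)
  expect_true(all(tm$map == 0))  # bm == rpe everywhere
  # mask mode: uniform 10-voxel RPEDC at dz 3.87 um -> 38.7 um everywhere
  a <- array(0L, c(60, 8, 4)); a[21:30, , ] <- 1L
  lab <- oct_labels(array(0L, dim(a)), array(0L, dim(a)), a, g)
  tm2 <- rpedc_thickness_map(lab)
  expect_true(all(tm2$map == 38.7))
  # empty columns are undefined
  a2 <- a; a2[, 3, ] <- 0L
  tm3 <- rpedc_thickness_map(oct_labels(array(0L, dim(a)), array(0L, dim(a)), a2, g))
  expect_true(all(is.na(tm3$map[, 3])))
  expect_true(all(!is.na(tm3$map[, -3])))
})

test_that("a single druse dominates the map at its apex", {
  prof <- small_profile()
  p <- phantom_params(seed = 77, drusen_count = 1,
                      drusen_height_px = c(5, 5), drusen_radius_cols = c(4, 4))
  s <- generate_surfaces(p, prof$grid)
  tm <- rpedc_thickness_map(rasterize_labels(s))
  apex_map <- which(tm$map == max(tm$map, na.rm = TRUE), arr.ind = TRUE)
  apex_true <- which(s$bm - s$rpe == max(s$bm - s$rpe), arr.ind = TRUE)
  expect_lte(min(abs(apex_map[, 2] - apex_true[1, 2])), 1)
})

test_that("PNG rendering clips, colours endpoints, and honours aspect", {
  dir <- withr::local_tempdir()
  g <- grid_spec(10, 12, 6, 4, 11.7, 47.2)
  mk <- function(vals) {
    structure(list(map = matrix(vals, 6, 12), dx = g$dx, dy = g$dy),
              class = "thickness_map")
  }
  p0 <- file.path(dir, "zero.png")
  render_thickness_png(mk(0), p0)
  img <- png::readPNG(p0)
  # all-zero map: uniform deep blue (#00008B)
  expect_true(all(abs(img[, , 1] - 0) < 2 / 255))
  expect_true(all(abs(img[, , 3] - 139 / 255) < 2 / 255))
  expect_equal(length(unique(as.vector(img[, , 3]))), 1)
  # clipping: 50 and 500 um give the identical deep red
  p1 <- file.path(dir, "clip.png")
  m <- mk(50); m$map[1, 1] <- 500
  render_thickness_png(m, p1)
  img2 <- png::readPNG(p1)
  expect_equal(length(unique(as.vector(img2[, , 1]))), 1)
  expect_true(all(abs(img2[, , 1] - 139 / 255) < 2 / 255))  # deep red #8B0000
  # lateral aspect: B-scan axis spans dy per row, A-scans dx per column
  expect_equal(dim(img)[1] / dim(img)[2],
               (6 * g$dy) / (12 * g$dx), tolerance = 0.1)
  expect_error(render_thickness_png(mk(0), p0, clip_lo = 50, clip_hi = 50),
               "clip_hi")
  # undefined cells render neutral gray
  m3 <- mk(25); m3$map[2, 2] <- NA
  p3 <- file.path(dir, "na.png")
  render_thickness_png(m3, p3)
  img3 <- png::readPNG(p3)
  gray_px <- img3[round(2 * dim(img3)[1] / 6), round(2 * dim(img3)[2] / 12), ]
  expect_equal(unname(gray_px), c(0.5, 0.5, 0.5), tolerance = 2 / 255)
  expect_s3_class(autoplot(mk(25)), "ggplot")
})
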