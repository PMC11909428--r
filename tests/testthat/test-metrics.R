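test_that("layer errors follow the exclusion rule", {
  gt <- matrix(10, 1, 4)
  pred <- matrix(c(11, 13, 10, NA), 1, 4)
  le <- layer_errors(pred, gt, "rpe")
  expect_equal(le$n_cols_used, 3)
  expect_equal(le$n_cols_excluded, 1)
  expect_equal(le$mae_px, 4 / 3)
  expect_equal(le$mse_px2, 10 / 3)
  expect_equal(layer_errors(gt, gt)$mae_px, 0)
  shift <- layer_errors(gt + 2, gt)
  expect_equal(shift$mae_px, 2)
  expect_equal(shift$mse_px2, 4)
  expect_error(layer_errors(matrix(NA_real_, 1, 4), gt), "no mutually defined")
})

test_that("mae never exceeds root mse", {
  set.seed(5)
  for (i in 1:20) {
    gt <- matrix(runif(40, 10, 50), 4, 10)
    pred <- gt + matrix(rnorm(40, sd = runif(1, 0.1, 5)), 4, 10)
    pred[sample(40, 5)] <- NA
    le <- layer_errors(pred, gt)
    expect_lte(le$mae_px, sqrt(le$mse_px2) + 1e-12)
  }
})

test_that("intergrader RMSE matches hand-computed cases", {
  a <- matrix(c(1, -1, 1, -1) + 10, 1, 4)
  b <- matrix(10, 1, 4)
  expect_equal(intergrader_rmse(a, b), 1)
  expect_equal(intergrader_rmse(b, b), 0)
  expect_equal(intergrader_rmse(b + 3, b), 3)
  expect_error(intergrader_rmse(matrix(NA_real_, 1, 4), b), "no mutually defined")
})

test_that("3D Dice matches identities and a brute-force oracle", {
  set.seed(9)
  a <- array(rbinom(1000, 1, 0.3), c(10, 10, 10))
  b <- array(rbinom(1000, 1, 0.3), c(10, 10, 10))
  brute <- function(x, y) {
    inter <- 0; sx <- 0; sy <- 0
    for (i in 1:10) for (j in 1:10) for (k in 1:10) {
      inter <- inter + x[i, j, k] * y[i, j, k]
      sx <- sx + x[i, j, k]; sy <- sy + y[i, j, k]
    }
    2 * inter / (sx + sy)
  }
  expect_equal(dice_3d(a, b), brute(a, b))
  expect_equal(dice_3d(a, b), dice_3d(b, a))
  expect_equal(dice_3d(a, a), 1)
  expect_equal(dice_3d(a, 1L - a), 0)
  # |A| = 100, B subset with |B| = 50 -> 2/3
  x <- array(0L, c(10, 10, 10)); x[1:100] <- 1L
  y <- array(0L, c(10, 10, 10)); y[1:50] <- 1L
  expect_equal(dice_3d(x, y), 2 / 3)
  # erosion of one operand cannot increase Dice against a superset
  expect_lte(dice_3d(x, y), dice_3d(x, x))
  expect_warning(d0 <- dice_3d(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))),
                 "empty")
  expect_equal(d0, 1)
  expect_error(dice_3d(a, array(0L, c(5, 5, 5))), "shape")
})

test_that("region volumes use the voxel volume in mm^3", {
  g <- grid_spec(50, 100, 50, 3.91, 11.7, 47.2)
  empty <- array(0L, c(50, 100, 50))
  expect_equal(region_volume_from_mask(empty, g), 0)
  one <- empty; one[25, 50, 25] <- 1L
  expect_equal(region_volume_from_mask(one, g), 3.91 * 11.7 * 47.2 * 1e-9)
  expect_equal(region_volume_from_mask(one, g), 2.159e-6, tolerance = 1e-3)
  # 10-voxel slab over a 100 x 50 lateral extent: closed form 0.10796 mm^3
  slab <- empty; slab[21:30, , ] <- 1L
  expect_equal(region_volume_from_mask(slab, g), 0.10796, tolerance = 1e-4)
  # surface version agrees on the same solid geometry
  upper <- matrix(20.5, 50, 100)  # rows 21..30 lie in [20.5, 30.5)
  lower <- upper + 10
  expect_equal(region_volume_from_surfaces(upper, lower, g),
               region_volume_from_mask(slab, g))
  expect_equal(region_volume_from_surfaces(upper, upper, g), 0)
  # violated ordering clamps to zero contribution
  expect_equal(region_volume_from_surfaces(upper, upper - 5, g), 0)
  # undefined columns contribute zero
  upper_na <- upper; upper_na[1, ] <- NA
  expect_lt(region_volume_from_surfaces(upper_na, lower, g),
            region_volume_from_surfaces(upper, lower, g))
})

test_that("Bland-Altman limits of agreement hold exactly", {
  ba <- bland_altman(c(11, 9), c(10, 10))  # d = {1, -1}
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_high, 2.772, tolerance = 1e-3)
  same <- bland_altman(1:5, 1:5)
  expect_equal(c(same$mean_diff, same$sd_diff, same$loa_low, same$loa_high),
               c(0, 0, 0, 0))
  const <- bland_altman(c(1.1, 2.1, 3.1), c(1, 2, 3))  # d constant 0.1
  expect_equal(const$sd_diff, 0)
  expect_equal(const$loa_low, 0.1)
  expect_equal(const$loa_high, 0.1)
  expect_error(bland_altman(1, 1), "at least 2")
  g <- glance(ba)
  expect_equal(g$loa_low, ba$loa_low)
  expect_s3_class(autoplot(ba), "ggplot")
})

test_that("paired t test matches the distribution oracle", {
  x <- c(3, 1, 4, 1); y <- c(1, 1, 2, 1)  # d = {2, 0, 2, 0}
  tt <- paired_ttest(x, y)
  expect_equal(tt$t, sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 3)
  expect_equal(tt$p_value, 0.1817, tolerance = 1e-3)
  oracle <- stats::t.test(x, y, paired = TRUE)
  expect_equal(tt$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(tt$p_value, oracle$p.value, tolerance = 1e-6)
  sym <- paired_ttest(c(10, 12), c(11, 11))  # d = {-1, 1}
  expect_equal(sym$t, 0)
  expect_equal(sym$p_value, 1)
  expect_error(paired_ttest(c(1, 2, 3) + 5, c(1, 2, 3)), "zero variance")
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(length(a))
    expect_equal(paired_ttest(a, b)$p_value,
                 stats::t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-6)
  }
})

test_that("intensity correlation behaves on constructed volumes", {
  g <- grid_spec(20, 25, 10, 4, 12, 48)
  set.seed(13)
  arr <- array(sample(0:255, 5000, replace = TRUE), c(20, 25, 10))
  a <- oct_volume(arr, g)
  expect_equal(intensity_correlation(a, a)$r, 1)
  inv <- oct_volume(255L - arr, g)
  expect_equal(intensity_correlation(a, inv)$r, -1)
  # independent noise volumes of 1e5 voxels decorrelate
  g2 <- grid_spec(50, 50, 40, 4, 12, 48)
  n1 <- oct_volume(array(sample(0:255, 1e5, replace = TRUE), c(50, 50, 40)), g2)
  n2 <- oct_volume(array(sample(0:255, 1e5, replace = TRUE), c(50, 50, 40)), g2)
  expect_lt(abs(intensity_correlation(n1, n2)$r), 0.02)
  flat <- oct_volume(array(7L, c(20, 25, 10)), g)
  expect_error(intensity_correlation(a, flat), "constant")
  h <- intensity_correlation(a, inv)$histograms
  expect_equal(sum(h$p_a), 1)
  expect_equal(sum(h$p_b), 1)
  expect_equal(nrow(h), 256)
})

test_that("AMD severity scores map to the published groups", {
  expect_equal(amdsc_group(0), "1")
  expect_equal(amdsc_group(1), "1")
  expect_equal(amdsc_group(2), "2")
  expect_equal(amdsc_group(5), "2")
  expect_equal(amdsc_group(6), "3")
  expect_equal(amdsc_group(8), "3")
  expect_equal(amdsc_group(9), "advanced")
  expect_equal(amdsc_group(11), "advanced")
  expect_equal(amdsc_group(c(0, 5, 8, 10)), c("1", "2", "3", "advanced"))
  expect_error(amdsc_group(12), "0, 11")
  expect_error(amdsc_group(-1), "0, 11")
  expect_error(amdsc_group(3.5), "integers")
})
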