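test_that("surfaces obey the anatomical construction", {
  prof <- small_profile()
  # no drusen: RPE sits exactly one band below BM everywhere
  p0 <- phantom_params(seed = 1, drusen_count = 0)
  s0 <- generate_surfaces(p0, prof$grid)
  expect_equal(max(abs(s0$bm - s0$rpe - p0$rpe_band_px)), 0)
  # a single druse raises the RPE by its height at the apex
  h <- 4.2
  p1 <- phantom_params(seed = 2, drusen_count = 1, drusen_height_px = c(h, h),
                       drusen_radius_cols = c(4, 4))
  s1 <- generate_surfaces(p1, prof$grid)
  expect_equal(max(s1$bm - s1$rpe), p1$rpe_band_px + h, tolerance = 0.5 / h)
  # NSR floor: RPE - ILM never thinner than nsr - foveal pit depth
  for (seed in 1:5) {
    p <- params_for_severity(sample(0:8, 1), seed = seed)
    s <- generate_surfaces(p, prof$grid)
    expect_true(min(s$rpe - s$ilm) >=
                  p$nsr_thickness_px - p$fovea_depth_px - p$undulation_px - 1e-9)
    expect_true(all(s$ilm <= s$rpe & s$rpe <= s$bm))
  }
})

test_that("surface generation is deterministic and depth-checked", {
  prof <- small_profile()
  p <- params_for_severity(7, seed = 11)
  expect_identical(generate_surfaces(p, prof$grid), generate_surfaces(p, prof$grid))
  shallow <- grid_spec(20, prof$grid$n_cols, prof$grid$n_bscans,
                       prof$grid$dz, prof$grid$dx, prof$grid$dy)
  expect_error(generate_surfaces(p, shallow), "n_rows")
})

test_that("rasterization uses the voxel-centre band test", {
  g <- grid_spec(40, 3, 1, 4, 12, 48)
  ilm <- matrix(c(10, 10.4, NA), 1, 3)
  rpe <- matrix(c(20, 20, NA), 1, 3)
  bm <- matrix(c(30, 30, NA), 1, 3)
  lab <- rasterize_labels(oct_surfaces(ilm, rpe, bm, g), band_halfwidth_px = 1.5)
  expect_equal(which(lab$ilm_band[, 1, 1] == 1), c(9, 10, 11))
  expect_equal(which(lab$ilm_band[, 2, 1] == 1), c(9, 10, 11))  # 10.4 +/- 1.5
  expect_equal(which(lab$rpedc[, 1, 1] == 1), 20:30)            # 11 voxels
  expect_equal(sum(lab$rpedc[, 1, 1]), 11)
  # undefined column is all-zero in every channel
  expect_equal(sum(lab$ilm_band[, 3, 1]) + sum(lab$rpe_band[, 3, 1]) +
                 sum(lab$rpedc[, 3, 1]), 0)
})

test_that("rendering is noise-free at zero speckle and deterministic", {
  ph <- small_phantom(severity = 3, seed = 5)
  prof <- ph$profile
  clean <- device_profile("clean", prof$grid, prof$reflectivity,
                          speckle_contrast = 0, n_averages = 1,
                          transfer_gamma = 1)
  v <- render_volume(ph$surfaces, clean, seed = 1)
  vals <- sort(unique(as.vector(v$intensities)))
  expect_true(all(vals %in% round(prof$reflectivity)))
  # vitreous voxels (above ILM) hold exactly the vitreous reflectivity
  expect_equal(v$intensities[1, 1, 1], unname(round(prof$reflectivity["vitreous"])))
  v1 <- render_volume(ph$surfaces, prof, seed = 42)
  v2 <- render_volume(ph$surfaces, prof, seed = 42)
  expect_identical(v1$intensities, v2$intensities)
  expect_false(identical(v1$intensities,
                         render_volume(ph$surfaces, prof, seed = 43)$intensities))
})

test_that("frame averaging reduces speckle variance like 1/sqrt(n)", {
  ph <- small_phantom(severity = 0, seed = 9)
  prof <- ph$profile
  mk <- function(n_avg) {
    device_profile("x", prof$grid, prof$reflectivity, speckle_contrast = 0.5,
                   n_averages = n_avg, transfer_gamma = 1)
  }
  vit <- function(v) {
    # rows well above the ILM are pure vitreous
    as.numeric(v$intensities[1:10, , ])
  }
  sd1 <- sd(vit(render_volume(ph$surfaces, mk(1), seed = 7)))
  sd16 <- sd(vit(render_volume(ph$surfaces, mk(16), seed = 7)))
  expect_equal(sd16 / sd1, 1 / 4, tolerance = 0.2)
})

test_that("two device profiles share anatomy but diverge in appearance", {
  pa <- small_profile("spectralis_like")
  pb_same_grid <- device_profile("b", pa$grid,
                                 device_preset("cirrus_like")$reflectivity,
                                 speckle_contrast = 0.55, n_averages = 1,
                                 transfer_gamma = 0.8)
  ph <- small_phantom(severity = 5, seed = 21)
  va <- render_volume(ph$surfaces, pa, seed = 3)
  vb <- render_volume(ph$surfaces, pb_same_grid, seed = 4)
  r <- intensity_correlation(va, vb)$r
  expect_lt(r, 0.9)
  expect_gt(r, 0)
})

test_that("perturb_surfaces simulates a second annotator", {
  ph <- small_phantom(severity = 4, seed = 13)
  expect_identical(perturb_surfaces(ph$surfaces, c(ilm = 0, rpe = 0, bm = 0)),
                   ph$surfaces)
  ann2 <- perturb_surfaces(ph$surfaces, c(ilm = 0.3, rpe = 1.3, bm = 1.0),
                           seed = 5)
  rmse_ilm <- intergrader_rmse(ph$surfaces$ilm, ann2$ilm)
  rmse_rpe <- intergrader_rmse(ph$surfaces$rpe, ann2$rpe)
  expect_lt(rmse_ilm, rmse_rpe)  # RPE annotation varies much more than ILM
  expect_gt(rmse_ilm, 0)
  # huge sigmas: ordering still clamped
  wild <- perturb_surfaces(ph$surfaces, c(ilm = 20, rpe = 20, bm = 20), seed = 6)
  expect_true(all(wild$ilm <= wild$rpe & wild$rpe <= wild$bm))
  expect_identical(perturb_surfaces(ph$surfaces, seed = 5),
                   perturb_surfaces(ph$surfaces, seed = 5))
})

test_that("device pairs share one anatomy across grids", {
  pa <- small_profile("spectralis_like")
  pb <- small_profile("cirrus_like")
  params <- params_for_severity(6, seed = 31)
  pair <- make_device_pair(params, pa, pb)
  # identical profiles: identical volumes
  twin <- make_device_pair(params, pa, pa)
  expect_identical(twin$vol_a$intensities, twin$vol_b$intensities)
  # per-device ground truths agree in physical units within one axial spacing
  back <- resample_surfaces(pair$surfaces_b, pa$grid, check_order = FALSE)
  for (ly in c("ilm", "rpe", "bm")) {
    both <- !is.na(back[[ly]])
    diff_um <- abs(back[[ly]] - pair$surfaces_a[[ly]])[both] * pa$grid$dz
    expect_lt(max(diff_um), max(pa$grid$dz, pb$grid$dz))
  }
  # ground-truth RPEDC volume is grid-invariant (common field of view)
  mask_a <- retilab:::common_fov_mask(pa$grid, pb$grid)
  mask_b <- retilab:::common_fov_mask(pb$grid, pa$grid)
  va <- region_volume_from_mask(
    retilab:::mask_labels_array(rasterize_labels(pair$surfaces_a)$rpedc, mask_a),
    pa$grid)
  vb <- region_volume_from_mask(
    retilab:::mask_labels_array(rasterize_labels(pair$surfaces_b)$rpedc, mask_b),
    pb$grid)
  expect_equal(va, vb, tolerance = 0.02)
})

test_that("cohorts are reproducible and severity drives drusen load", {
  pa <- small_profile("spectralis_like")
  pb <- small_profile("cirrus_like")
  co1 <- make_cohort(4, profiles = list(pa, pb), seed = 17)
  co2 <- make_cohort(4, profiles = list(pa, pb), seed = 17)
  expect_identical(co1, co2)
  expect_error(make_cohort(0, profiles = list(pa, pb)), "n_cases")
  expect_error(make_cohort(2, severity_mix = numeric(0),
                           profiles = list(pa, pb)), "severity_mix")
  # severity 0/1 cases carry no drusen by construction
  g1 <- make_cohort(3, severity_mix = c(`1` = 1), profiles = list(pa, pb),
                    seed = 23)
  expect_true(all(vapply(g1$case, function(cs) cs$params$drusen_count,
                         numeric(1)) == 0))
  # Group 3 mean ground-truth RPEDC volume exceeds Group 1's
  g3 <- make_cohort(8, severity_mix = c(`3` = 1), profiles = list(pa, pb),
                    seed = 23)
  g1b <- make_cohort(8, severity_mix = c(`1` = 1), profiles = list(pa, pb),
                     seed = 29)
  vol_of <- function(co) {
    mean(vapply(co$case, function(cs) {
      region_volume_from_mask(cs$labels_a$rpedc, cs$labels_a$grid)
    }, numeric(1)))
  }
  expect_gt(vol_of(g3), vol_of(g1b))
})
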