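#' Phantom anatomy parameters
#'
#' Describes one synthetic macular anatomy: a smooth internal limiting membrane
#' with a central foveal pit, a near-planar (tilted) Bruch's membrane, and an
#' RPE that sits `rpe_band_px` above BM except where drusen (smooth radially
#' symmetric Gaussian caps) elevate it. Drusen load is the severity driver:
#' [params_for_severity()] maps an AMD severity score 0-11 to drusen counts and
#' height ranges monotonically.
#'
#' All pixel-valued fields are in voxels of the reference grid passed to
#' [generate_surfaces()]; lateral fields are in A-scan columns.
#'
#' @param seed integer seed; all randomness of the case flows from it.
#' @param severity_score integer AMD severity score in `[0, 11]`.
#' @param fovea_depth_px depth of the foveal pit (px).
#' @param fovea_radius_cols Gaussian radius of the pit (columns).
#' @param nsr_thickness_px baseline ILM-to-RPE separation (px).
#' @param rpe_band_px RPE band thickness = undisturbed RPE-to-BM distance (px).
#' @param drusen_count number of drusen (>= 0).
#' @param drusen_height_px length-2 range of drusen apex heights (px).
#' @param drusen_radius_cols length-2 range of drusen Gaussian radii (columns).
#' @param tilt_px_per_col global retina tilt (px per column).
#' @param bm_row_frac BM baseline depth as a fraction of `n_rows`.
#' @param undulation_px amplitude of the gentle seeded ILM waviness (px).
#' @return A `phantom_params` object.
#' @export
phantom_params <- function(seed, severity_score = 0L,
                           fovea_depth_px = 8, fovea_radius_cols = 16,
                           nsr_thickness_px = 18, rpe_band_px = 3,
                           drusen_count = 0L,
                           drusen_height_px = c(1, 2),
                           drusen_radius_cols = c(3, 8),
                           tilt_px_per_col = 0.02,
                           bm_row_frac = 0.62,
                           undulation_px = 0.3) {
  if (severity_score < 0 || severity_score > 11) {
    rlang::abort("phantom_params: severity_score must lie in [0, 11]")
  }
  if (nsr_thickness_px <= 0 || rpe_band_px <= 0) {
    rlang::abort("phantom_params: thicknesses must be positive")
  }
  if (drusen_count < 0) rlang::abort("phantom_params: drusen_count must be >= 0")
  if (any(drusen_height_px < 0)) rlang::abort("phantom_params: drusen heights must be >= 0")
  if (fovea_depth_px < 0 || fovea_radius_cols <= 0) {
    rlang::abort("phantom_params: foveal pit shape parameters invalid")
  }
  structure(
    list(seed = as.integer(seed), severity_score = as.integer(severity_score),
         fovea_depth_px = fovea_depth_px, fovea_radius_cols = fovea_radius_cols,
         nsr_thickness_px = nsr_thickness_px, rpe_band_px = rpe_band_px,
         drusen_count = as.integer(drusen_count),
         drusen_height_px = sort(as.numeric(drusen_height_px)),
         drusen_radius_cols = sort(as.numeric(drusen_radius_cols)),
         tilt_px_per_col = tilt_px_per_col, bm_row_frac = bm_row_frac,
         undulation_px = undulation_px),
    class = "phantom_params"
  )
}

#' Map an AMD severity score to phantom parameters
#'
#' Scores 0-1 (no AMD) carry no drusen; from score 2 upwards the drusen count
#' and apex-height range grow linearly, so expected drusen (RPEDC) volume is
#' monotone in severity, mirroring the grouping in which Group 3 (scores 6-8)
#' has the largest drusen and drusen volumes.
#'
#' @param severity_score integer in `[0, 11]`.
#' @param seed integer case seed.
#' @param ... overrides forwarded to [phantom_params()].
#' @return A `phantom_params` object.
#' @export
params_for_severity <- function(severity_score, seed, ...) {
  s <- as.integer(severity_score)
  if (s < 0 || s > 11) rlang::abort("params_for_severity: score must lie in [0, 11]")
  if (s <= 1) {
    count <- 0L
    h <- c(0, 0)
  } else {
    count <- 2L * (s - 1L)
    base <- 0.8 + 0.45 * s
    h <- c(0.6 * base, 1.4 * base)
  }
  phantom_params(seed = seed, severity_score = s, drusen_count = count,
                 drusen_height_px = h, ...)
}

# Run code under a seed without disturbing the caller's RNG state.
with_rng <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Lateral voxel-centre coordinates (um), centred on the field of view.
lateral_coords_um <- function(grid) {
  list(u = ((seq_len(grid$n_cols) - 0.5) - grid$n_cols / 2) * grid$dx,
       v = ((seq_len(grid$n_bscans) - 0.5) - grid$n_bscans / 2) * grid$dy)
}

#' Generate ground-truth layer surfaces for one phantom
#'
#' Builds the ILM/RPE/BM surface triplet on `grid` from `params`. BM is a
#' tilted plane; RPE is BM minus the band thickness, elevated by the drusen
#' field; ILM drapes over the RPE at the neurosensory-retina thickness, with
#' the foveal pit and a gentle seeded waviness. The anatomical ordering
#' `ilm <= rpe <= bm` holds everywhere by construction, and the result is
#' deterministic for a fixed `params$seed`.
#'
#' @param params a [phantom_params()] object.
#' @param grid the [grid_spec()] to sample on.
#' @return An [oct_surfaces()] object (fully defined).
#' @export
generate_surfaces <- function(params, grid) {
  stopifnot(inherits(params, "phantom_params"), is_grid_spec(grid))
  bm0 <- params$bm_row_frac * grid$n_rows
  max_h <- if (params$drusen_count > 0) max(params$drusen_height_px) else 0
  tilt_span <- abs(params$tilt_px_per_col) * grid$n_cols / 2
  need <- ceiling(bm0 + tilt_span + 2) # rows needed below the retina
  top_need <- bm0 - tilt_span - params$rpe_band_px - max_h -
    params$nsr_thickness_px - params$undulation_px
  if (need > grid$n_rows || top_need < 1) {
    rlang::abort(sprintf(
      "generate_surfaces: grid too shallow for this anatomy (need n_rows >= %d and >= %d rows above BM baseline; have %d)",
      need, ceiling(bm0 - top_need + 1), grid$n_rows))
  }
  lc <- lateral_coords_um(grid)
  u_cols <- (seq_len(grid$n_cols) - 0.5) - grid$n_cols / 2

  with_rng(params$seed, {
    # bm[b, x]
    bm <- matrix(rep(bm0 + params$tilt_px_per_col * u_cols, each = grid$n_bscans),
                 grid$n_bscans, grid$n_cols)
    drusen <- matrix(0, grid$n_bscans, grid$n_cols)
    if (params$drusen_count > 0) {
      ext <- grid_extent_um(grid)
      for (i in seq_len(params$drusen_count)) {
        uc <- stats::runif(1, -0.45, 0.45) * ext[["width"]]
        vc <- stats::runif(1, -0.45, 0.45) * ext[["slow"]]
        h <- stats::runif(1, params$drusen_height_px[1], params$drusen_height_px[2])
        rho <- stats::runif(1, params$drusen_radius_cols[1],
                            params$drusen_radius_cols[2]) * grid$dx
        d2 <- outer((lc$v - vc)^2, (lc$u - uc)^2, `+`)
        drusen <- drusen + h * exp(-d2 / (2 * rho^2))
      }
    }
    rpe <- bm - params$rpe_band_px - drusen
    pit <- params$fovea_depth_px *
      exp(-outer(lc$v^2, lc$u^2, `+`) / (2 * (params$fovea_radius_cols * grid$dx)^2))
    ph <- stats::runif(2, 0, 2 * pi)
    und <- params$undulation_px *
      (0.6 * cos(2 * pi * outer(rep(1, grid$n_bscans), u_cols) /
                   (grid$n_cols / 1.7) + ph[1]) +
       0.4 * cos(2 * pi * outer((seq_len(grid$n_bscans) - grid$n_bscans / 2),
                                rep(1, grid$n_cols)) / (grid$n_bscans / 1.3) + ph[2]))
    ilm <- rpe - params$nsr_thickness_px + pit + und
    oct_surfaces(ilm, rpe, bm, grid)
  })
}

#' Rasterize surfaces into multi-pixel label channels
#'
#' Voxel-centre test: voxel `(r, x, b)` belongs to the ILM band iff
#' `|r - ilm(b, x)| <= band_halfwidth_px` (analogously for the RPE band), and
#' to the RPEDC region iff `rpe(b, x) <= r <= bm(b, x)`. Columns with an
#' undefined surface produce all-zero columns in the channels that need it.
#'
#' @param surfaces an [oct_surfaces()] object.
#' @param band_halfwidth_px half-width of the ILM/RPE bands in voxels
#'   (default 1.5, i.e. about 3-voxel bands).
#' @return An [oct_labels()] object on the surfaces' grid.
#' @export
rasterize_labels <- function(surfaces, band_halfwidth_px = 1.5) {
  stopifnot(inherits(surfaces, "oct_surfaces"))
  g <- surfaces$grid
  rows <- seq_len(g$n_rows)
  dims <- c(g$n_rows, g$n_cols, g$n_bscans)
  ilm_a <- array(0L, dims); rpe_a <- array(0L, dims); rpedc_a <- array(0L, dims)
  for (b in seq_len(g$n_bscans)) {
    z_ilm <- surfaces$ilm[b, ]; z_rpe <- surfaces$rpe[b, ]; z_bm <- surfaces$bm[b, ]
    band <- function(z) {
      m <- abs(outer(rows, z, `-`)) <= band_halfwidth_px
      m[, is.na(z)] <- FALSE
      m
    }
    ilm_a[, , b] <- band(z_ilm)
    rpe_a[, , b] <- band(z_rpe)
    reg <- outer(rows, z_rpe, `>=`) & outer(rows, z_bm, `<=`)
    reg[, is.na(z_rpe) | is.na(z_bm)] <- FALSE
    rpedc_a[, , b] <- reg
  }
  oct_labels(ilm_a, rpe_a, rpedc_a, g)
}

#' Render an intensity volume for a device profile
#'
#' Assigns each voxel a compartment (vitreous, neurosensory retina, RPE band,
#' RPEDC interior, choroid) by its centre's position relative to the surfaces,
#' multiplies the compartment reflectivity by gamma-distributed speckle with
#' the profile's contrast (variance divided by the frame-averaging count),
#' applies the profile's monotone gamma transfer, and quantizes to `[0, 255]`.
#' Deterministic for a fixed seed. Surfaces on a different grid are first
#' resampled onto the profile's grid.
#'
#' @param surfaces an [oct_surfaces()] object.
#' @param profile a [device_profile()].
#' @param seed integer seed for the speckle field.
#' @param rpe_halfwidth_px half-width of the bright RPE band around the RPE
#'   surface (default 1.5, matching [rasterize_labels()]).
#' @return An [oct_volume()] on the profile's grid.
#' @export
render_volume <- function(surfaces, profile, seed, rpe_halfwidth_px = 1.5) {
  stopifnot(inherits(surfaces, "oct_surfaces"),
            inherits(profile, "device_profile"))
  if (!grids_equal(surfaces$grid, profile$grid)) {
    surfaces <- resample_surfaces(surfaces, profile$grid)
  }
  g <- profile$grid
  refl <- profile$reflectivity
  rows <- seq_len(g$n_rows)
  vol <- array(0, c(g$n_rows, g$n_cols, g$n_bscans))
  for (b in seq_len(g$n_bscans)) {
    z_ilm <- surfaces$ilm[b, ]; z_rpe <- surfaces$rpe[b, ]; z_bm <- surfaces$bm[b, ]
    # default vitreous; undefined columns stay vitreous
    sl <- matrix(refl[["vitreous"]], g$n_rows, g$n_cols)
    ok <- !is.na(z_ilm) & !is.na(z_rpe) & !is.na(z_bm)
    if (any(ok)) {
      z_ilm[!ok] <- Inf; z_rpe[!ok] <- Inf; z_bm[!ok] <- Inf
      in_nsr <- outer(rows, z_ilm, `>=`) & outer(rows, z_rpe, `<`)
      in_reg <- outer(rows, z_rpe, `>=`) & outer(rows, z_bm, `<=`)
      in_rpe <- abs(outer(rows, z_rpe, `-`)) <= rpe_halfwidth_px
      in_rpe[, !ok] <- FALSE
      below <- outer(rows, z_bm, `>`)
      below[, !ok] <- FALSE
      sl[in_nsr] <- refl[["nsr"]]
      sl[below] <- refl[["choroid"]]
      sl[in_reg] <- refl[["rpedc"]]
      sl[in_rpe] <- refl[["rpe"]]
    }
    vol[, , b] <- sl
  }
  with_rng(seed, {
    if (profile$speckle_contrast > 0) {
      # average of n iid Gamma(k, rate k) speckle draws ~ Gamma(nk, rate nk)
      k <- profile$n_averages / profile$speckle_contrast^2
      vol <- vol * stats::rgamma(length(vol), shape = k, rate = k)
    }
    out <- 255 * (pmin(pmax(vol / 255, 0), 1))^profile$transfer_gamma
    oct_volume(array(as.integer(round(pmin(pmax(out, 0), 255))), dim(vol)),
               g, device_name = profile$name)
  })
}

#' Simulate a second annotator by perturbing surfaces
#'
#' Adds a smooth, laterally correlated, zero-mean field with the given
#' per-layer marginal standard deviations, then re-clamps the anatomical
#' ordering and the grid depth range. With all-zero sigmas the input is
#' returned unchanged. Deterministic per seed.
#'
#' @param surfaces an [oct_surfaces()] object.
#' @param sigma_px named numeric: marginal standard deviations in voxels for
#'   `ilm`, `rpe`, `bm`. Defaults mirror the pattern that RPE annotation
#'   variability greatly exceeds ILM variability.
#' @param seed integer seed.
#' @param corr_cols lateral correlation scale of the perturbation (columns).
#' @return An [oct_surfaces()] object.
#' @export
perturb_surfaces <- function(surfaces,
                             sigma_px = c(ilm = 0.3, rpe = 1.3, bm = 1.0),
                             seed = 1L, corr_cols = 6) {
  stopifnot(inherits(surfaces, "oct_surfaces"))
  if (any(sigma_px < 0)) rlang::abort("perturb_surfaces: sigmas must be >= 0")
  miss <- setdiff(surface_layers, names(sigma_px))
  if (length(miss)) sigma_px[miss] <- 0
  if (all(sigma_px[surface_layers] == 0)) return(surfaces)
  g <- surfaces$grid
  with_rng(seed, {
    smooth_field <- function(sigma) {
      if (sigma == 0) return(matrix(0, g$n_bscans, g$n_cols))
      w <- stats::dnorm(seq(-3, 3, length.out = 2 * ceiling(corr_cols) + 1))
      noise <- matrix(stats::rnorm(g$n_bscans * g$n_cols), g$n_bscans, g$n_cols)
      sm <- t(apply(noise, 1, function(r) {
        as.numeric(stats::filter(c(rev(r), r, rev(r)), w / sum(w),
                                 sides = 2))[g$n_cols + seq_len(g$n_cols)]
      }))
      sm * sigma / stats::sd(as.numeric(sm))
    }
    ilm <- surfaces$ilm + smooth_field(sigma_px[["ilm"]])
    rpe <- surfaces$rpe + smooth_field(sigma_px[["rpe"]])
    bm <- surfaces$bm + smooth_field(sigma_px[["bm"]])
    clamp <- function(m) pmin(pmax(m, 1), g$n_rows)
    ilm <- clamp(ilm)
    rpe <- clamp(pmax(rpe, ilm))
    bm <- clamp(pmax(bm, rpe))
    oct_surfaces(ilm, rpe, bm, g)
  })
}

#' Physical-coordinate surfaces of a device pair
#'
#' @keywords internal
physical_surfaces_um <- function(surfaces) {
  g <- surfaces$grid
  ext <- grid_extent_um(g)
  df <- tidy.oct_surfaces(surfaces)
  df$u_um <- ((df$col - 0.5) - g$n_cols / 2) * g$dx
  df$v_um <- ((df$bscan - 0.5) - g$n_bscans / 2) * g$dy
  df$z_um <- (df$row_px - 0.5) * g$dz - ext[["depth"]] / 2
  df[, c("layer", "bscan", "col", "u_um", "v_um", "z_um")]
}

#' Render one anatomy under two device profiles
#'
#' One phantom anatomy is generated once and sampled onto each profile's grid
#' over the common (centre-aligned) field of view, then rendered per device
#' with the same speckle seed, so identical profiles yield identical volumes.
#' The returned physical surface table is device-independent (micrometre
#' coordinates relative to the shared field-of-view centre).
#'
#' @param params a [phantom_params()] object.
#' @param profile_a,profile_b [device_profile()] objects; fields of view must
#'   overlap.
#' @return A `device_pair` list: `vol_a`, `vol_b` ([oct_volume()]),
#'   `surfaces_a`, `surfaces_b` (per-grid [oct_surfaces()]),
#'   `physical_um` (tibble with `layer`, `u_um`, `v_um`, `z_um`), `params`.
#' @export
make_device_pair <- function(params, profile_a, profile_b) {
  stopifnot(inherits(profile_a, "device_profile"),
            inherits(profile_b, "device_profile"))
  common_fov(profile_a$grid, profile_b$grid)  # errors when disjoint
  surf_a <- generate_surfaces(params, profile_a$grid)
  surf_b <- resample_surfaces(surf_a, profile_b$grid)
  render_seed <- (params$seed + 1000003L) %% .Machine$integer.max
  vol_a <- render_volume(surf_a, profile_a, seed = render_seed)
  vol_b <- render_volume(surf_b, profile_b, seed = render_seed)
  structure(list(vol_a = vol_a, vol_b = vol_b,
                 surfaces_a = surf_a, surfaces_b = surf_b,
                 physical_um = physical_surfaces_um(surf_a),
                 params = params),
            class = "device_pair")
}

amdsc_scores_in_group <- list(`1` = 0:1, `2` = 2:5, `3` = 6:8, advanced = 9:11)

#' Generate a seeded phantom cohort
#'
#' Draws severity scores from a mix over the AMD severity groups, builds one
#' device pair per case, and rasterizes per-device ground-truth labels. The
#' cohort is fully reproducible from `seed`.
#'
#' @param n_cases number of cases (>= 1).
#' @param severity_mix named probabilities over groups `"1"`, `"2"`, `"3"`,
#'   `"advanced"`; must sum to 1.
#' @param profiles list of two [device_profile()]s (device A is the training
#'   device).
#' @param seed integer cohort seed.
#' @param band_halfwidth_px forwarded to [rasterize_labels()].
#' @param stratify when TRUE, allocate cases to groups deterministically in
#'   proportion to `severity_mix` (largest-remainder rounding) instead of
#'   sampling the group labels; scores within groups are still sampled.
#' @return A tibble with one row per case: `case_id`, `seed`,
#'   `severity_score`, `group`, and a `case` list-column holding the
#'   `device_pair` plus `labels_a`/`labels_b`.
#' @export
make_cohort <- function(n_cases,
                        severity_mix = c(`1` = 1 / 3, `2` = 1 / 3, `3` = 1 / 3),
                        profiles = list(device_preset("spectralis_like"),
                                        device_preset("cirrus_like")),
                        seed = 1L, band_halfwidth_px = 1.5, stratify = FALSE) {
  if (n_cases < 1) rlang::abort("make_cohort: n_cases must be >= 1")
  if (length(severity_mix) == 0 || abs(sum(severity_mix) - 1) > 1e-8) {
    rlang::abort("make_cohort: severity_mix must be non-empty and sum to 1")
  }
  if (!all(names(severity_mix) %in% names(amdsc_scores_in_group))) {
    rlang::abort("make_cohort: severity_mix names must be among 1, 2, 3, advanced")
  }
  groups <- if (stratify) {
    base <- floor(n_cases * severity_mix)
    rem <- n_cases - sum(base)
    if (rem > 0) {
      extra <- order(n_cases * severity_mix - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    rep(names(severity_mix), times = base)
  } else {
    with_rng(seed, {
      sample(names(severity_mix), n_cases, replace = TRUE, prob = severity_mix)
    })
  }
  scores <- with_rng(seed + 1L, {
    vapply(groups, function(gp) {
      pool <- amdsc_scores_in_group[[gp]]
      pool[sample.int(length(pool), 1)]
    }, integer(1))
  })
  rows <- purrr::map(seq_len(n_cases), function(i) {
    case_seed <- (seed + 104729L * i) %% .Machine$integer.max
    params <- params_for_severity(scores[i], seed = case_seed)
    pair <- make_device_pair(params, profiles[[1]], profiles[[2]])
    labels_a <- rasterize_labels(pair$surfaces_a, band_halfwidth_px)
    labels_b <- rasterize_labels(pair$surfaces_b, band_halfwidth_px)
    tibble::tibble(
      case_id = sprintf("case%03d", i), seed = case_seed,
      severity_score = scores[i], group = groups[i],
      case = list(c(pair, list(labels_a = labels_a, labels_b = labels_b)))
    )
  })
  dplyr::bind_rows(rows)
}
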