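#' Experiment configuration
#'
#' Describes the full cross-device validation experiment: train both (or one)
#' compact architecture(s) on phantoms rendered by the first device profile
#' only, then evaluate on held-out phantoms imaged by both profiles — the
#' four test settings arch x device. Test volumes from the second device are
#' resampled onto the training profile's grid before inference (configurable
#' direction convention), and all evaluation is restricted to the common
#' field of view of the two devices.
#'
#' @param n_train training cases (volumes); each contributes all its B-scans.
#' @param n_test held-out test cases (device pairs).
#' @param severity_mix named group probabilities (see [make_cohort()]); the
#'   test cohort is stratified so every group is represented.
#' @param profile_names two device preset names; the first is the training
#'   device.
#' @param scale grid down-scaling factor passed to [device_preset()]
#'   (default 4: quarter-scale grids).
#' @param archs architectures to train.
#' @param train a [train_config()] (its `arch` field is overridden per run).
#' @param seed master seed; cohort and per-arch training seeds derive from it.
#' @param out_dir optional output directory for tables, maps and the manifest.
#' @param rpedc_mode `"mask"` (default; RPEDC volume and Dice from the region
#'   channel) or `"surface"` (volume from the extracted RPE/p95-BM surfaces).
#' @param annotator_sigma per-layer simulated second-annotator sigmas (px),
#'   passed to [perturb_surfaces()].
#' @param band_halfwidth_px label band half-width (px).
#' @param n_thickness_maps number of test cases to render as en face
#'   thickness-map PNG sets when `out_dir` is given.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(n_train = 5L, n_test = 9L,
                              severity_mix = c(`1` = 1 / 3, `2` = 1 / 3, `3` = 1 / 3),
                              profile_names = c("spectralis_like", "cirrus_like"),
                              scale = 4L,
                              archs = c("encoder_decoder", "dilated"),
                              train = train_config(),
                              seed = 1L, out_dir = NULL,
                              rpedc_mode = c("mask", "surface"),
                              annotator_sigma = c(ilm = 0.3, rpe = 1.3, bm = 1.0),
                              band_halfwidth_px = 1.5,
                              n_thickness_maps = 3L) {
  rpedc_mode <- match.arg(rpedc_mode)
  if (n_train < 1) rlang::abort("experiment_config: n_train must be >= 1")
  if (length(archs) < 1) rlang::abort("experiment_config: need at least one arch")
  stopifnot(inherits(train, "train_config"))
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 severity_mix = severity_mix, profile_names = profile_names,
                 scale = as.integer(scale), archs = archs, train = train,
                 seed = as.integer(seed), out_dir = out_dir,
                 rpedc_mode = rpedc_mode, annotator_sigma = annotator_sigma,
                 band_halfwidth_px = band_halfwidth_px,
                 n_thickness_maps = as.integer(n_thickness_maps)),
            class = "experiment_config")
}

# Logical [n_bscans, n_cols] mask of grid `a` columns inside the common
# lateral field of view of grids a and b (centre-aligned).
common_fov_mask <- function(a, b) {
  fov <- common_fov(a, b)
  lc <- lateral_coords_um(a)
  in_u <- abs(lc$u) <= fov$width_mm * 1000 / 2 + 1e-9
  in_v <- abs(lc$v) <= fov$slow_mm * 1000 / 2 + 1e-9
  outer(in_v, in_u, `&`)
}

mask_surfaces <- function(surfaces, mask) {
  m <- surfaces
  for (ly in surface_layers) m[[ly]][!mask] <- NA_real_
  oct_surfaces(m$ilm, m$rpe, m$bm, surfaces$grid, check_order = FALSE)
}

mask_labels_array <- function(arr, mask) {
  # zero out columns outside the evaluation field of view
  for (b in seq_len(dim(arr)[3])) {
    arr[, !mask[b, ], b] <- 0L
  }
  arr
}

#' Run the full cross-device validation experiment
#'
#' Generates a seeded training cohort on the first device profile and trains
#' each architecture on its B-scans; generates a stratified held-out test
#' cohort of device pairs; evaluates every architecture on both devices
#' (second-device volumes resampled onto the training grid); and assembles
#' the analogue tables: layer MAE/MSE by severity group, simulated
#' intergrader RMSE, volumetric RPEDC Dice by group, NSR/RPEDC volumetric
#' errors, Bland-Altman limits of agreement, and the cross-vs-same paired
#' t tests. When `config$out_dir` is set, tables (JSON + CSV), thickness-map
#' PNGs, an event log and a provenance manifest are written there.
#'
#' @param config an [experiment_config()].
#' @return A results list: `models`, `loss_history`, `per_case_layers`,
#'   `per_case_regions`, `intergrader`, `tables` (list of tibbles),
#'   `bland_altman` (per setting and overall, for RPEDC and NSR),
#'   `intensity`, `manifest`, `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$out_dir
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file.path(out_dir, "events.jsonl")
  }
  log_event <- function(stage, ...) {
    msg <- list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ...)
    message(sprintf("[retilab] %s", stage))
    if (!is.null(log_con)) {
      cat(jsonlite::toJSON(msg, auto_unbox = TRUE), "\n",
          file = log_con, append = TRUE)
    }
  }
  run_stage <- function(stage, expr) {
    log_event(stage)
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("experiment stage '%s' failed: %s", stage,
                           conditionMessage(e)))
    })
  }

  profiles <- run_stage("profiles", {
    lapply(config$profile_names, device_preset, scale = config$scale)
  })
  grid_a <- profiles[[1]]$grid
  eval_mask <- common_fov_mask(grid_a, profiles[[2]]$grid)

  train_cohort <- run_stage("simulate_train_cohort", {
    make_cohort(config$n_train, config$severity_mix, profiles,
                seed = config$seed, band_halfwidth_px = config$band_halfwidth_px)
  })
  test_cohort <- run_stage("simulate_test_cohort", {
    make_cohort(config$n_test, config$severity_mix, profiles,
                seed = config$seed + 1L,
                band_halfwidth_px = config$band_halfwidth_px, stratify = TRUE)
  })

  train_cases <- purrr::map(train_cohort$case, function(cs) {
    list(volume = cs$vol_a, labels = cs$labels_a)
  })
  models <- list()
  loss_history <- list()
  for (i in seq_along(config$archs)) {
    arch <- config$archs[i]
    models[[arch]] <- run_stage(paste0("train_", arch), {
      cfg <- config$train
      cfg$arch <- arch
      cfg$seed <- config$train$seed + i - 1L
      train_model(build_model(cfg), train_cases, cfg)
    })
    loss_history[[arch]] <- dplyr::mutate(models[[arch]]$loss_history,
                                          arch = arch, .before = 1)
  }

  sigma <- config$annotator_sigma
  eval_one <- function(row_i) {
    cs <- test_cohort$case[[row_i]]
    meta <- tibble::tibble(case_id = test_cohort$case_id[row_i],
                           group = test_cohort$group[row_i],
                           severity_score = test_cohort$severity_score[row_i])
    gt_surf <- mask_surfaces(cs$surfaces_a, eval_mask)
    gt_rpedc <- mask_labels_array(cs$labels_a$rpedc, eval_mask)
    vol_b_on_a <- resample_volume(cs$vol_b, grid_a)
    layer_rows <- list(); region_rows <- list()
    for (arch in config$archs) {
      for (device in c("same", "cross")) {
        vol <- if (device == "same") cs$vol_a else vol_b_on_a
        pred <- predict_labels(models[[arch]], vol)
        pred_surf <- mask_surfaces(extract_standard_surfaces(pred), eval_mask)
        for (ly in c("ilm", "rpe")) {
          # a model that predicts no usable columns yields an NA row rather
          # than aborting the whole experiment
          le <- tryCatch(layer_errors(pred_surf[[ly]], gt_surf[[ly]], layer = ly),
                         error = function(e) tibble::tibble(
                           layer = ly, mae_px = NA_real_, mse_px2 = NA_real_,
                           n_cols_used = 0L,
                           n_cols_excluded = length(gt_surf[[ly]])))
          layer_rows[[length(layer_rows) + 1]] <-
            dplyr::bind_cols(meta, tibble::tibble(arch = arch, device = device), le)
        }
        pred_rpedc <- mask_labels_array(pred$rpedc, eval_mask)
        dice <- dice_3d(pred_rpedc, gt_rpedc)
        rpedc_pred <- if (config$rpedc_mode == "mask") {
          region_volume_from_mask(pred_rpedc, grid_a)
        } else {
          region_volume_from_surfaces(pred_surf$rpe, pred_surf$bm, grid_a)
        }
        rpedc_ref <- region_volume_from_mask(gt_rpedc, grid_a)
        nsr_pred <- region_volume_from_surfaces(pred_surf$ilm, pred_surf$rpe,
                                                grid_a)
        nsr_ref <- region_volume_from_surfaces(gt_surf$ilm, gt_surf$rpe, grid_a)
        region_rows[[length(region_rows) + 1]] <- dplyr::bind_cols(
          meta,
          tibble::tibble(arch = arch, device = device, dice = dice,
                         rpedc_pred_mm3 = rpedc_pred, rpedc_ref_mm3 = rpedc_ref,
                         nsr_pred_mm3 = nsr_pred, nsr_ref_mm3 = nsr_ref))
      }
    }
    # simulated second annotator on the second device's native grid
    ann2 <- perturb_surfaces(cs$surfaces_b, sigma,
                             seed = (cs$params$seed + 7L) %% .Machine$integer.max)
    inter <- purrr::map_dfr(surface_layers, function(ly) {
      dplyr::bind_cols(meta, tibble::tibble(
        layer = ly, rmse_px = intergrader_rmse(cs$surfaces_b[[ly]], ann2[[ly]])))
    })
    list(layers = dplyr::bind_rows(layer_rows),
         regions = dplyr::bind_rows(region_rows), intergrader = inter)
  }

  evals <- run_stage("evaluate_settings", {
    purrr::map(seq_len(nrow(test_cohort)), eval_one)
  })
  per_case_layers <- dplyr::bind_rows(purrr::map(evals, "layers"))
  per_case_regions <- dplyr::bind_rows(purrr::map(evals, "regions"))
  intergrader <- dplyr::bind_rows(purrr::map(evals, "intergrader"))

  tables <- run_stage("tables", {
    errors_by_group <- per_case_layers |>
      dplyr::group_by(.data$arch, .data$device, .data$group, .data$layer) |>
      dplyr::summarise(n = dplyr::n(),
                       mae_mean = mean(.data$mae_px, na.rm = TRUE),
                       mae_sd = stats::sd(.data$mae_px, na.rm = TRUE),
                       mse_mean = mean(.data$mse_px2, na.rm = TRUE),
                       mse_sd = stats::sd(.data$mse_px2, na.rm = TRUE),
                       .groups = "drop")
    dice_by_group <- per_case_regions |>
      dplyr::group_by(.data$arch, .data$device, .data$group) |>
      dplyr::summarise(n = dplyr::n(), dice_mean = mean(.data$dice),
                       dice_sd = stats::sd(.data$dice), .groups = "drop")
    intergrader_by_group <- intergrader |>
      dplyr::group_by(.data$group, .data$layer) |>
      dplyr::summarise(n = dplyr::n(), rmse_px = mean(.data$rmse_px),
                       .groups = "drop")
    volume_errors <- per_case_regions |>
      dplyr::group_by(.data$arch, .data$device) |>
      dplyr::summarise(
        n = dplyr::n(),
        nsr_err_mean = mean(.data$nsr_pred_mm3 - .data$nsr_ref_mm3),
        nsr_err_sd = stats::sd(.data$nsr_pred_mm3 - .data$nsr_ref_mm3),
        rpedc_err_mean = mean(.data$rpedc_pred_mm3 - .data$rpedc_ref_mm3),
        rpedc_err_sd = stats::sd(.data$rpedc_pred_mm3 - .data$rpedc_ref_mm3),
        .groups = "drop")
    cross_vs_same <- per_case_layers |>
      tidyr::pivot_wider(id_cols = c("case_id", "arch", "layer"),
                         names_from = "device", values_from = "mae_px") |>
      tidyr::drop_na("same", "cross") |>
      dplyr::group_by(.data$arch, .data$layer) |>
      dplyr::reframe({
        # too few usable pairs or zero-variance differences give an NA row
        x <- .data$cross
        y <- .data$same
        tryCatch(paired_ttest(x, y),
                 error = function(e) tibble::tibble(
                   t = NA_real_, df = NA_integer_, p_value = NA_real_,
                   mean_diff = NA_real_, n = length(x)))
      })
    list(errors_by_group = errors_by_group, dice_by_group = dice_by_group,
         intergrader_by_group = intergrader_by_group,
         volume_errors = volume_errors, cross_vs_same = cross_vs_same)
  })

  ba <- run_stage("bland_altman", {
    per_setting <- per_case_regions |>
      dplyr::group_by(.data$arch, .data$device) |>
      dplyr::group_map(function(df, key) {
        list(arch = key$arch, device = key$device,
             rpedc = bland_altman(df$rpedc_pred_mm3, df$rpedc_ref_mm3),
             nsr = bland_altman(df$nsr_pred_mm3, df$nsr_ref_mm3))
      })
    overall <- list(
      rpedc = bland_altman(per_case_regions$rpedc_pred_mm3,
                           per_case_regions$rpedc_ref_mm3),
      nsr = bland_altman(per_case_regions$nsr_pred_mm3,
                         per_case_regions$nsr_ref_mm3))
    list(per_setting = per_setting, overall = overall)
  })

  intensity <- run_stage("intensity_correlation", {
    cs <- test_cohort$case[[1]]
    vol_b_on_a <- resample_volume(cs$vol_b, grid_a)
    keep_b <- which(apply(eval_mask, 1, any))
    keep_x <- which(apply(eval_mask, 2, any))
    crop <- function(v) oct_volume(
      v$intensities[, keep_x, keep_b, drop = FALSE],
      grid_spec(v$grid$n_rows, length(keep_x), length(keep_b),
                v$grid$dz, v$grid$dx, v$grid$dy), v$device_name)
    intensity_correlation(crop(cs$vol_a), crop(vol_b_on_a))
  })

  manifest <- run_stage("manifest", {
    resolved <- config
    resolved$out_dir <- NULL
    list(
      package_version = as.character(utils::packageVersion("retilab")),
      r_version = R.version.string,
      seed = config$seed,
      config_hash = rlang::hash(resolved),
      cases = dplyr::bind_rows(
        dplyr::mutate(train_cohort[c("case_id", "seed", "severity_score", "group")],
                      role = "train"),
        dplyr::mutate(test_cohort[c("case_id", "seed", "severity_score", "group")],
                      role = "test"))
    )
  })

  if (!is.null(out_dir)) {
    run_stage("write_outputs", {
      for (nm in names(tables)) {
        write_metrics(tables[[nm]], file.path(out_dir, paste0(nm, ".json")))
      }
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
      cfg <- config
      cfg$train <- unclass(cfg$train)
      yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_resolved.yaml"))
      n_maps <- min(config$n_thickness_maps, nrow(test_cohort))
      for (i in seq_len(n_maps)) {
        cs <- test_cohort$case[[i]]
        cid <- test_cohort$case_id[i]
        gt_map <- rpedc_thickness_map(cs$labels_a)
        render_thickness_png(gt_map, file.path(out_dir, sprintf("%s_gt.png", cid)))
        vol_b_on_a <- resample_volume(cs$vol_b, grid_a)
        for (arch in config$archs) {
          pred <- predict_labels(models[[arch]], vol_b_on_a)
          render_thickness_png(rpedc_thickness_map(pred),
                               file.path(out_dir, sprintf("%s_%s.png", cid, arch)))
        }
      }
    })
  }
  log_event("done")

  list(models = models, loss_history = dplyr::bind_rows(loss_history),
       per_case_layers = per_case_layers, per_case_regions = per_case_regions,
       intergrader = intergrader, tables = tables, bland_altman = ba,
       intensity = intensity, manifest = manifest, config = config)
}
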