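#' Layer distance errors with the exclusion rule
#'
#' MAE and MSE between a predicted and a reference surface map, computed only
#' over columns where BOTH are defined; columns where either surface is
#' interrupted or missing are excluded (and counted). Errors are aggregated
#' over all mutually defined columns of the volume.
#'
#' @param pred,gt numeric matrices `[n_bscans, n_cols]` of row positions
#'   (`NA` = undefined), or [oct_surfaces()] from which `layer` is taken.
#' @param layer layer name used for labelling (and for selecting the map when
#'   surface sets are passed).
#' @return A one-row tibble: `layer`, `mae_px`, `mse_px2`, `n_cols_used`,
#'   `n_cols_excluded`.
#' @export
layer_errors <- function(pred, gt, layer = "layer") {
  if (inherits(pred, "oct_surfaces")) pred <- pred[[layer]]
  if (inherits(gt, "oct_surfaces")) gt <- gt[[layer]]
  if (!all(dim(pred) == dim(gt))) {
    rlang::abort("layer_errors: surface maps must share a grid")
  }
  both <- !is.na(pred) & !is.na(gt)
  n_used <- sum(both)
  if (n_used == 0) {
    rlang::abort("layer_errors: no mutually defined columns")
  }
  d <- pred[both] - gt[both]
  mae <- mean(abs(d))
  mse <- mean(d^2)
  stopifnot(mae <= sqrt(mse) + 1e-12)  # Cauchy-Schwarz sanity
  tibble::tibble(layer = layer, mae_px = mae, mse_px2 = mse,
                 n_cols_used = n_used,
                 n_cols_excluded = length(pred) - n_used)
}

#' Intergrader RMSE between two surface maps
#'
#' Root-mean-square difference over mutually defined columns (same exclusion
#' rule as [layer_errors()]).
#'
#' @param a,b numeric matrices `[n_bscans, n_cols]` (`NA` = undefined).
#' @return RMSE in pixels.
#' @export
intergrader_rmse <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    rlang::abort("intergrader_rmse: surface maps must share a grid")
  }
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) rlang::abort("intergrader_rmse: no mutually defined columns")
  sqrt(mean((a[both] - b[both])^2))
}

#' Volumetric (3D) Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` over the whole volume — never per B-scan, since
#' per-B-scan Dice is misleadingly dominated by B-scans with tiny foreground.
#' Two empty masks are defined as Dice 1.0 (perfect agreement on absence; a
#' warning is emitted).
#'
#' @param a,b binary arrays of equal shape (0/1).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_3d <- function(a, b) {
  if (!all(dim(a) == dim(b))) rlang::abort("dice_3d: shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    rlang::warn("dice_3d: both masks empty; defining Dice as 1")
    return(1.0)
  }
  2 * sum(a * b) / (sa + sb)
}

#' Region volume from a binary mask
#'
#' Voxel count times the voxel volume `dz * dx * dy`, converted to cubic
#' millimetres. The package's default quantitative RPEDC volume: counted on
#' the region channel directly (the p95 BM surface is for visualization).
#'
#' @param mask binary array on `grid`.
#' @param grid a [grid_spec()].
#' @return Volume in mm^3.
#' @export
region_volume_from_mask <- function(mask, grid) {
  stopifnot(is_grid_spec(grid))
  if (!all(dim(mask) == c(grid$n_rows, grid$n_cols, grid$n_bscans))) {
    rlang::abort("region_volume_from_mask: mask shape must match grid")
  }
  sum(mask) * grid$dz * grid$dx * grid$dy * 1e-9
}

#' Region volume bounded by two surfaces
#'
#' Sums `max(lower - upper, 0) * dz * dx * dy` over mutually defined columns
#' (`lower` is the deeper surface, i.e. larger row). Columns lacking either
#' surface contribute zero. Used for the neurosensory-retina volume (ILM to
#' RPE) and, optionally, a surface-based RPEDC volume (RPE to BM).
#'
#' @param upper,lower numeric matrices `[n_bscans, n_cols]` of row positions.
#' @param grid a [grid_spec()].
#' @return Volume in mm^3.
#' @export
region_volume_from_surfaces <- function(upper, lower, grid) {
  stopifnot(is_grid_spec(grid))
  if (!all(dim(upper) == dim(lower))) {
    rlang::abort("region_volume_from_surfaces: surface maps must share a grid")
  }
  thick <- pmax(lower - upper, 0)
  thick[is.na(thick)] <- 0
  sum(thick) * grid$dz * grid$dx * grid$dy * 1e-9
}

#' Bland-Altman agreement analysis
#'
#' Differences `pred - ref`; mean, sample standard deviation (n-1 denominator)
#' and limits of agreement `mean +/- 1.96 * sd`.
#'
#' @param pred,ref equal-length numeric vectors (n >= 2); units are carried
#'   through (mm^3 for the volume analyses).
#' @return A `bland_altman` object (also a list with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the per-pair `means`/`diffs`).
#' @export
bland_altman <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    rlang::abort("bland_altman: inputs must have equal length")
  }
  n <- length(pred)
  if (n < 2) rlang::abort("bland_altman: need at least 2 pairs")
  d <- pred - ref
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = n,
         means = (pred + ref) / 2, diffs = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d mean=%.4g sd=%.4g LOA=[%.4g, %.4g]\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean = x$means, diff = x$diffs)
}

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' Bland-Altman plot
#'
#' @param object a [bland_altman()] result.
#' @param ... unused.
#' @return A ggplot: per-pair mean vs difference with the mean difference and
#'   the limits of agreement as horizontal lines.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy.bland_altman(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of pair", y = "Difference (pred - ref)",
                  title = sprintf("Bland-Altman: mean %.3g, LOA [%.3g, %.3g]",
                                  object$mean_diff, object$loa_low,
                                  object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Two-sided paired t test
#'
#' Classical paired t statistic `mean(d) / (sd(d) / sqrt(n))` with `n - 1`
#' degrees of freedom and a two-sided p value from the t distribution.
#' A zero-variance difference vector signals degenerate input and raises an
#' error rather than reporting p = 0.
#'
#' @param x,y equal-length numeric vectors (n >= 2).
#' @return A tibble with `t`, `df`, `p_value`, `mean_diff`, `n`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("paired_ttest: equal lengths required")
  n <- length(x)
  if (n < 2) rlang::abort("paired_ttest: need n >= 2")
  d <- x - y
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) {
    rlang::abort("paired_ttest: zero variance of differences (degenerate input)")
  }
  t_stat <- mean(d) / (s / sqrt(n))
  tibble::tibble(t = t_stat, df = n - 1,
                 p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
                 mean_diff = mean(d), n = n)
}

#' Voxelwise intensity correlation between two volumes
#'
#' Pearson correlation over paired voxels (resample one volume onto the
#' other's grid first), a p value from the t transform of r, and 256-bin
#' occurrence-probability histograms of each volume's raw 0-255 intensities.
#'
#' @param a,b [oct_volume()] objects on the same grid.
#' @return A list: `r`, `p_value`, `n`, and `histograms` (tibble with
#'   `intensity`, `p_a`, `p_b`).
#' @export
intensity_correlation <- function(a, b) {
  stopifnot(inherits(a, "oct_volume"), inherits(b, "oct_volume"))
  if (!all(dim(a$intensities) == dim(b$intensities))) {
    rlang::abort("intensity_correlation: volumes must share a grid (resample first)")
  }
  va <- as.numeric(a$intensities); vb <- as.numeric(b$intensities)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    rlang::abort("intensity_correlation: constant volume, correlation undefined")
  }
  n <- length(va)
  r <- stats::cor(va, vb)
  t_stat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  hist_p <- function(v) tabulate(v + 1L, nbins = 256L) / length(v)
  list(r = r, p_value = 2 * stats::pt(-abs(t_stat), df = n - 2), n = n,
       histograms = tibble::tibble(intensity = 0:255,
                                   p_a = hist_p(a$intensities),
                                   p_b = hist_p(b$intensities)))
}

#' AMD severity group from an AMD severity score
#'
#' Scores 0-1 form Group 1 (no AMD), 2-5 Group 2 (early AMD), 6-8 Group 3
#' (intermediate AMD with medium to large drusen); 9-11 (central geographic
#' atrophy / neovascular AMD) are reported separately as "advanced".
#'
#' @param score integer vector of severity scores in `[0, 11]`.
#' @return Character vector of group labels (`"1"`, `"2"`, `"3"`, `"advanced"`).
#' @export
amdsc_group <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 11) ||
      any(score != round(score))) {
    rlang::abort("amdsc_group: scores must be integers in [0, 11]")
  }
  dplyr::case_when(
    score <= 1 ~ "1",
    score <= 5 ~ "2",
    score <= 8 ~ "3",
    TRUE ~ "advanced"
  )
}
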