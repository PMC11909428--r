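#' Extract a sub-pixel surface from a label channel at a percentile
#'
#' For every (B-scan, column) A-scan the labelled voxel rows are pooled and
#' sorted, and the surface position is the linearly interpolated percentile at
#' rank position `(p/100) * (n - 1)` (closest-ranks interpolation, retaining
#' sub-pixel values). Columns with no labelled voxel are undefined. Gaps within
#' a column are not filtered: all labelled voxels of the column count.
#'
#' With `percentile = 0` / `100` the first / last labelled row is returned
#' exactly; the result is nondecreasing in the percentile.
#'
#' @param labels an [oct_labels()] object.
#' @param channel `"ilm_band"`, `"rpe_band"` or `"rpedc"`.
#' @param percentile percentile in `[0, 100]`.
#' @return Numeric matrix `[n_bscans, n_cols]` of sub-pixel rows (`NA` where
#'   the column holds no label).
#' @export
extract_surface <- function(labels, channel, percentile) {
  stopifnot(inherits(labels, "oct_labels"))
  if (!channel %in% label_channels) {
    rlang::abort(sprintf("extract_surface: unknown channel '%s'", channel))
  }
  if (!is.finite(percentile) || percentile < 0 || percentile > 100) {
    rlang::abort("extract_surface: percentile must lie in [0, 100]")
  }
  g <- labels$grid
  a <- labels[[channel]]
  p <- percentile / 100
  out <- matrix(NA_real_, g$n_bscans, g$n_cols)
  for (b in seq_len(g$n_bscans)) {
    sl <- a[, , b]
    cnt <- colSums(sl)
    for (x in which(cnt > 0)) {
      rows <- which(sl[, x] == 1L)
      n <- length(rows)
      h <- p * (n - 1)
      lo <- floor(h)
      out[b, x] <- rows[lo + 1] * (1 - (h - lo)) +
        rows[min(lo + 1, n - 1) + 1] * (h - lo)
    }
  }
  out
}

#' Extract the standard ILM/RPE/BM surfaces from label channels
#'
#' The package's standard extraction: ILM and RPE at the 50th percentile of
#' their band channels, and BM at the 95th percentile of the RPEDC region
#' channel (near the lower RPEDC edge just above the choroid; the 95th rather
#' than the 100th percentile avoids pinning BM on noisy last voxels). No
#' ordering is enforced: network predictions may violate it, and the metric
#' layer's exclusion rule handles missing columns.
#'
#' By default the p95 BM surface is intended for visualization and thickness
#' maps; quantitative RPEDC volume and Dice default to the region channel
#' itself (see [region_volume_from_mask()]).
#'
#' @param labels an [oct_labels()] object.
#' @return An [oct_surfaces()] object (`check_order = FALSE`).
#' @export
extract_standard_surfaces <- function(labels) {
  oct_surfaces(
    ilm = extract_surface(labels, "ilm_band", 50),
    rpe = extract_surface(labels, "rpe_band", 50),
    bm = extract_surface(labels, "rpedc", 95),
    labels$grid, check_order = FALSE
  )
}
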