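#' OCT intensity volume
#'
#' @param intensities numeric array `[n_rows, n_cols, n_bscans]` with values in
#'   `[0, 255]` (stored as integers).
#' @param grid the [grid_spec()] the array lives on.
#' @param device_name identifier of the device profile that rendered it.
#' @return An `oct_volume` object.
#' @export
oct_volume <- function(intensities, grid, device_name = "unknown") {
  stopifnot(is_grid_spec(grid))
  d <- dim(intensities)
  if (is.null(d) || length(d) != 3L ||
      !all(d == c(grid$n_rows, grid$n_cols, grid$n_bscans))) {
    rlang::abort("oct_volume: array dimensions must match the grid")
  }
  if (anyNA(intensities) || min(intensities) < 0 || max(intensities) > 255) {
    rlang::abort("oct_volume: intensities must lie in [0, 255]")
  }
  storage.mode(intensities) <- "integer"
  structure(list(intensities = intensities, grid = grid,
                 device_name = as.character(device_name)),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf("<oct_volume> device=%s\n", x$device_name))
  print(x$grid)
  invisible(x)
}

#' Multi-channel binary label volume
#'
#' Three independent (possibly overlapping) binary channels over one grid:
#' a multi-pixel band around the ILM, a band around the RPE, and the filled
#' RPE-drusen-complex (RPEDC) region between RPE and BM. The RPE band is
#' geometrically contained in the RPEDC region, which is why the channels are
#' independent binaries rather than mutually exclusive classes.
#'
#' @param ilm_band,rpe_band,rpedc binary (0/1) arrays `[n_rows, n_cols, n_bscans]`.
#' @param grid the [grid_spec()].
#' @return An `oct_labels` object.
#' @export
oct_labels <- function(ilm_band, rpe_band, rpedc, grid) {
  stopifnot(is_grid_spec(grid))
  dims <- c(grid$n_rows, grid$n_cols, grid$n_bscans)
  for (nm in c("ilm_band", "rpe_band", "rpedc")) {
    a <- get(nm)
    if (is.null(dim(a)) || !all(dim(a) == dims)) {
      rlang::abort(sprintf("oct_labels: %s dimensions must match the grid", nm))
    }
    if (anyNA(a) || !all(a %in% c(0L, 1L))) {
      rlang::abort(sprintf("oct_labels: %s must be binary 0/1", nm))
    }
  }
  mk <- function(a) { storage.mode(a) <- "integer"; a }
  structure(list(ilm_band = mk(ilm_band), rpe_band = mk(rpe_band),
                 rpedc = mk(rpedc), grid = grid),
            class = "oct_labels")
}

#' @export
print.oct_labels <- function(x, ...) {
  cat(sprintf("<oct_labels> foreground fractions: ilm=%.3f rpe=%.3f rpedc=%.3f\n",
              mean(x$ilm_band), mean(x$rpe_band), mean(x$rpedc)))
  print(x$grid)
  invisible(x)
}

label_channels <- c("ilm_band", "rpe_band", "rpedc")

#' Sub-pixel layer surfaces
#'
#' Per-(B-scan, column) axial positions of the ILM, RPE and BM surfaces, as
#' real-valued row coordinates on a grid (voxel centres at integer rows; see
#' [grid_spec()]). `NA` marks columns where a surface is undefined
#' (interrupted or missing). Wherever all three are defined the anatomical
#' ordering `ilm <= rpe <= bm` holds for ground truth (rows increase with
#' depth); extracted predictions may violate it and are handled by the metric
#' layer.
#'
#' @param ilm,rpe,bm numeric matrices `[n_bscans, n_cols]` of row coordinates
#'   (or `NA`).
#' @param grid the [grid_spec()].
#' @param check_order enforce the `ilm <= rpe <= bm` invariant (default TRUE;
#'   surfaces extracted from network predictions set this to FALSE).
#' @return An `oct_surfaces` object.
#' @export
oct_surfaces <- function(ilm, rpe, bm, grid, check_order = TRUE) {
  stopifnot(is_grid_spec(grid))
  dims <- c(grid$n_bscans, grid$n_cols)
  for (nm in c("ilm", "rpe", "bm")) {
    m <- get(nm)
    if (is.null(dim(m)) || !all(dim(m) == dims)) {
      rlang::abort(sprintf("oct_surfaces: %s must be a [n_bscans, n_cols] matrix", nm))
    }
    bad <- !is.na(m) & (m < 0.5 | m > grid$n_rows + 0.5)
    if (any(bad)) {
      rlang::abort(sprintf("oct_surfaces: %s has positions outside the grid depth", nm))
    }
  }
  if (check_order) {
    ok <- is.na(ilm) | is.na(rpe) | is.na(bm) |
      (ilm <= rpe + 1e-9 & rpe <= bm + 1e-9)
    if (!all(ok)) {
      rlang::abort("oct_surfaces: ordering ilm <= rpe <= bm violated")
    }
  }
  structure(list(ilm = ilm, rpe = rpe, bm = bm, grid = grid),
            class = "oct_surfaces")
}

surface_layers <- c("ilm", "rpe", "bm")

#' @export
print.oct_surfaces <- function(x, ...) {
  nd <- vapply(x[surface_layers], function(m) mean(!is.na(m)), numeric(1))
  cat(sprintf("<oct_surfaces> defined fractions: ilm=%.3f rpe=%.3f bm=%.3f\n",
              nd[1], nd[2], nd[3]))
  print(x$grid)
  invisible(x)
}

#' Tidy a surface set into a long tibble
#'
#' @param x an [oct_surfaces()] object.
#' @param ... unused.
#' @return A tibble with columns `layer`, `bscan`, `col`, `row_px` (`NA` where
#'   the surface is undefined).
#' @export
tidy.oct_surfaces <- function(x, ...) {
  purrr::map_dfr(surface_layers, function(ly) {
    m <- x[[ly]]
    tibble::tibble(
      layer = ly,
      bscan = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      row_px = as.vector(m)
    )
  })
}

#' Rebuild an oct_surfaces object from its tidy form
#'
#' Inverse of [tidy.oct_surfaces()].
#'
#' @param df tibble with columns `layer`, `bscan`, `col`, `row_px`.
#' @param grid the [grid_spec()] the surfaces live on.
#' @param check_order passed to [oct_surfaces()].
#' @return An [oct_surfaces()] object.
#' @export
surfaces_from_tidy <- function(df, grid, check_order = TRUE) {
  mats <- lapply(surface_layers, function(ly) {
    m <- matrix(NA_real_, grid$n_bscans, grid$n_cols)
    sub <- df[df$layer == ly, ]
    m[cbind(sub$bscan, sub$col)] <- sub$row_px
    m
  })
  oct_surfaces(mats[[1]], mats[[2]], mats[[3]], grid, check_order = check_order)
}
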