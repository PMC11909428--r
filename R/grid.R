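#' Voxel grid of an OCT volume
#'
#' An OCT volume is indexed `(row, col, bscan)`: `row` is the axial (depth)
#' index with row 1 at the vitreous (top of the B-scan), `col` indexes A-scans
#' within a B-scan, and `bscan` indexes B-scans along the slow axis. Physical
#' spacings are in micrometres. Voxel `i` along an axis with spacing `s` spans
#' `[(i-1)*s, i*s)` and has its centre at `(i-0.5)*s`, so integer coordinates
#' refer to voxel centres.
#'
#' @param n_rows,n_cols,n_bscans positive integer voxel counts
#'   (axial rows, A-scans per B-scan, B-scans).
#' @param dz,dx,dy positive spacings in micrometres (axial, within-B-scan
#'   lateral, between-B-scan).
#' @return A `grid_spec` object.
#' @examples
#' grid_spec(496, 768, 121, 3.87, 11.7, 58.7)
#' @export
grid_spec <- function(n_rows, n_cols, n_bscans, dz, dx, dy) {
  counts <- c(n_rows = n_rows, n_cols = n_cols, n_bscans = n_bscans)
  spacings <- c(dz = dz, dx = dx, dy = dy)
  if (any(counts < 1) || any(counts != round(counts))) {
    rlang::abort("grid_spec: voxel counts must be integers >= 1")
  }
  if (any(!is.finite(spacings)) || any(spacings <= 0)) {
    rlang::abort("grid_spec: spacings must be positive")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         n_bscans = as.integer(n_bscans),
         dz = as.numeric(dz), dx = as.numeric(dx), dy = as.numeric(dy)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels @ %.4g x %.4g x %.4g um\n",
              x$n_rows, x$n_cols, x$n_bscans, x$dz, x$dx, x$dy))
  invisible(x)
}

is_grid_spec <- function(x) inherits(x, "grid_spec")

grids_equal <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols && a$n_bscans == b$n_bscans &&
    isTRUE(all.equal(c(a$dz, a$dx, a$dy), c(b$dz, b$dx, b$dy)))
}

#' Physical field-of-view extent
#'
#' @param depth_mm,width_mm,slow_mm positive extents in millimetres along the
#'   axial, lateral (within-B-scan) and slow (between-B-scan) axes.
#' @return A `physical_extent` object.
#' @export
physical_extent <- function(depth_mm, width_mm, slow_mm) {
  v <- c(depth_mm = depth_mm, width_mm = width_mm, slow_mm = slow_mm)
  if (any(!is.finite(v)) || any(v <= 0)) {
    rlang::abort("physical_extent: extents must be positive")
  }
  structure(as.list(v), class = "physical_extent")
}

#' @export
print.physical_extent <- function(x, ...) {
  cat(sprintf("<physical_extent> %.4g x %.4g x %.4g mm (depth x width x slow)\n",
              x$depth_mm, x$width_mm, x$slow_mm))
  invisible(x)
}

#' Extent of a grid in micrometres
#'
#' @param grid a [grid_spec()].
#' @return Named numeric vector `c(depth, width, slow)` in micrometres.
#' @export
grid_extent_um <- function(grid) {
  stopifnot(is_grid_spec(grid))
  c(depth = grid$n_rows * grid$dz,
    width = grid$n_cols * grid$dx,
    slow  = grid$n_bscans * grid$dy)
}

#' Voxel spacing from a field-of-view extent
#'
#' `spacing = 1000 * extent_mm / n_pixels` micrometres. This reproduces the
#' printed device spacings, e.g. a 2 mm axial depth over 512 rows gives
#' 3.90625 um (printed 3.91) and a 9 mm width over 768 A-scans gives
#' 11.71875 um (printed 11.7).
#'
#' @param extent_mm field-of-view extent in millimetres.
#' @param n_pixels number of voxels spanning it.
#' @return Spacing in micrometres.
#' @export
spacing_from_extent <- function(extent_mm, n_pixels) {
  if (!is.finite(extent_mm) || extent_mm <= 0) {
    rlang::abort("spacing_from_extent: extent must be positive")
  }
  if (!is.finite(n_pixels) || n_pixels < 1 || n_pixels != round(n_pixels)) {
    rlang::abort("spacing_from_extent: n_pixels must be an integer >= 1")
  }
  1000 * extent_mm / n_pixels
}

#' Common field of view of two grids
#'
#' Fields of view are aligned by their physical centres (the package's
#' registration convention; phantom device pairs are constructed co-centred).
#' The common field of view is then the per-axis intersection of the centred
#' extents. An optional lateral offset between the two centres can be supplied;
#' a disjoint overlap raises an error.
#'
#' @param a,b [grid_spec()] objects.
#' @param offset_mm optional length-2 lateral offset (width, slow) of `b`'s
#'   centre relative to `a`'s, in millimetres.
#' @return A [physical_extent()] of the overlap.
#' @export
common_fov <- function(a, b, offset_mm = c(0, 0)) {
  stopifnot(is_grid_spec(a), is_grid_spec(b))
  ea <- grid_extent_um(a) / 1000
  eb <- grid_extent_um(b) / 1000
  off <- c(0, offset_mm)  # no axial offset
  lo <- pmax(-ea / 2, off - eb / 2)
  hi <- pmin(ea / 2, off + eb / 2)
  if (any(hi - lo <= 0)) {
    rlang::abort("common_fov: fields of view do not overlap")
  }
  physical_extent(hi[[1]] - lo[[1]], hi[[2]] - lo[[2]], hi[[3]] - lo[[3]])
}

#' Device appearance profile
#'
#' Bundles a voxel grid with a compact rendering model of device appearance:
#' mean reflectivity (0-255) per tissue compartment, multiplicative speckle
#' contrast (coefficient of variation of the speckle field), a frame-averaging
#' count that divides the speckle variance, and a monotone gamma intensity
#' transfer.
#'
#' @param name identifier string.
#' @param grid a [grid_spec()].
#' @param reflectivity named numeric vector with entries `vitreous`, `nsr`,
#'   `rpe`, `rpedc`, `choroid`, each in `[0, 255]`.
#' @param speckle_contrast coefficient of variation of the single-frame
#'   multiplicative speckle (>= 0).
#' @param n_averages frame-averaging count (integer >= 1); averaging `n`
#'   frames divides the speckle variance by `n`.
#' @param transfer_gamma exponent of the monotone intensity transfer
#'   `I -> 255 * (I/255)^gamma` (> 0).
#' @return A `device_profile` object.
#' @seealso [device_preset()] for the two built-in profiles.
#' @export
device_profile <- function(name, grid, reflectivity, speckle_contrast = 0.5,
                           n_averages = 1, transfer_gamma = 1) {
  stopifnot(is_grid_spec(grid))
  needed <- c("vitreous", "nsr", "rpe", "rpedc", "choroid")
  if (!all(needed %in% names(reflectivity))) {
    rlang::abort(paste0("device_profile: reflectivity needs entries ",
                        paste(needed, collapse = ", ")))
  }
  reflectivity <- reflectivity[needed]
  if (any(reflectivity < 0 | reflectivity > 255)) {
    rlang::abort("device_profile: reflectivities must lie in [0, 255]")
  }
  if (speckle_contrast < 0) rlang::abort("device_profile: speckle_contrast must be >= 0")
  if (n_averages < 1) rlang::abort("device_profile: n_averages must be >= 1")
  if (transfer_gamma <= 0) rlang::abort("device_profile: transfer_gamma must be > 0")
  structure(
    list(name = as.character(name), grid = grid,
         reflectivity = reflectivity,
         speckle_contrast = as.numeric(speckle_contrast),
         n_averages = as.integer(n_averages),
         transfer_gamma = as.numeric(transfer_gamma)),
    class = "device_profile"
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("<device_profile> %s\n", x$name))
  print(x$grid)
  cat(sprintf("  reflectivity: %s\n",
              paste(sprintf("%s=%g", names(x$reflectivity), x$reflectivity),
                    collapse = " ")))
  cat(sprintf("  speckle_contrast=%g n_averages=%d gamma=%g\n",
              x$speckle_contrast, x$n_averages, x$transfer_gamma))
  invisible(x)
}

#' Built-in device profiles
#'
#' Two presets emulating the qualitative appearance differences between a
#' frame-averaged, high-contrast scanner ("spectralis_like": 496 x 768 x 121
#' voxels at 3.87 x 11.7 x 58.7 um, heavy frame averaging, full-range
#' compartment contrast) and an unaveraged scanner with a compressed mid-range
#' transfer ("cirrus_like": 512 x 512 x 128 voxels at 3.91 x 11.7 x 47.2 um,
#' single frame, gamma < 1). `scale` shrinks the voxel counts and inflates the
#' spacings by the same factor, preserving the physical field of view; the
#' default `scale = 4` gives desk-scale grids (e.g. 124 x 192 x 30), while
#' `scale = 1` returns the full printed grids.
#'
#' @param name `"spectralis_like"` or `"cirrus_like"`.
#' @param scale integer down-scaling factor (>= 1) applied to all three axes.
#' @return A [device_profile()].
#' @export
device_preset <- function(name = c("spectralis_like", "cirrus_like"), scale = 4) {
  name <- match.arg(name)
  if (scale < 1 || scale != round(scale)) {
    rlang::abort("device_preset: scale must be an integer >= 1")
  }
  full <- switch(name,
    spectralis_like = grid_spec(496, 768, 121, 3.87, 11.7, 58.7),
    cirrus_like     = grid_spec(512, 512, 128, 3.91, 11.7, 47.2)
  )
  grid <- grid_spec(full$n_rows %/% scale, full$n_cols %/% scale,
                    full$n_bscans %/% scale,
                    full$dz * scale, full$dx * scale, full$dy * scale)
  switch(name,
    spectralis_like = device_profile(
      name, grid,
      reflectivity = c(vitreous = 10, nsr = 110, rpe = 225, rpedc = 170,
                       choroid = 60),
      speckle_contrast = 0.5, n_averages = 12, transfer_gamma = 1
    ),
    cirrus_like = device_profile(
      name, grid,
      reflectivity = c(vitreous = 30, nsr = 115, rpe = 185, rpedc = 150,
                       choroid = 85),
      speckle_contrast = 0.55, n_averages = 1, transfer_gamma = 0.8
    )
  )
}
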