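# Continuous source index of each target voxel centre along one axis, with the
# two fields of view aligned by their physical centres. Voxel i's centre sits
# at (i - 0.5) * s, so target centre t maps to source index t/s_src + 0.5 after
# shifting both extents to a common centre.
axis_source_index <- function(n_src, s_src, n_tgt, s_tgt) {
  centre_src <- n_src * s_src / 2
  centre_tgt <- n_tgt * s_tgt / 2
  t_phys <- (seq_len(n_tgt) - 0.5) * s_tgt - centre_tgt  # centred coordinate
  (t_phys + centre_src) / s_src + 0.5
}

# Linear interpolation of an array along one axis at continuous indices `at`,
# clamping to the edges (nearest-edge value outside the source).
interp_axis <- function(arr, at, axis) {
  n <- dim(arr)[axis]
  at <- pmin(pmax(at, 1), n)
  if (n == 1L) {
    i0 <- rep(1L, length(at)); f <- rep(0, length(at))
  } else {
    i0 <- pmin(floor(at), n - 1L); f <- at - i0
  }
  i1 <- pmin(i0 + 1L, n)
  take <- function(idx) {
    switch(axis, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
           arr[, , idx, drop = FALSE])
  }
  d <- dim(arr); d[axis] <- length(at)
  wfull <- array(0, d)
  wfull[] <- switch(axis, f, rep(f, each = d[1]), rep(f, each = d[1] * d[2]))
  take(i0) * (1 - wfull) + take(i1) * wfull
}

#' Resample a volume onto another grid
#'
#' Trilinear interpolation at the target voxel centres, with the two fields of
#' view aligned by their physical centres. Samples outside the source take the
#' nearest-edge value; the result is quantized back to `[0, 255]`. Resampling
#' a volume onto its own grid is the identity.
#'
#' @param vol an [oct_volume()].
#' @param target a [grid_spec()] whose field of view overlaps the source's.
#' @return An [oct_volume()] on `target`.
#' @export
resample_volume <- function(vol, target) {
  stopifnot(inherits(vol, "oct_volume"), is_grid_spec(target))
  src <- vol$grid
  common_fov(src, target)  # errors when disjoint
  if (grids_equal(src, target)) {
    return(oct_volume(vol$intensities, target, vol$device_name))
  }
  a <- vol$intensities
  storage.mode(a) <- "double"
  a <- interp_axis(a, axis_source_index(src$n_rows, src$dz, target$n_rows, target$dz), 1L)
  a <- interp_axis(a, axis_source_index(src$n_cols, src$dx, target$n_cols, target$dx), 2L)
  a <- interp_axis(a, axis_source_index(src$n_bscans, src$dy, target$n_bscans, target$dy), 3L)
  oct_volume(array(as.integer(round(pmin(pmax(a, 0), 255))), dim(a)),
             target, vol$device_name)
}

# Bilinear interpolation of one surface matrix [n_bscans, n_cols] of physical
# depths, at target lateral centres. Weights of NA neighbours are dropped and
# the rest renormalized; a target column outside the source lateral footprint
# (beyond half a voxel past the outermost centres) becomes NA.
interp_surface_lateral <- function(m, src, tgt) {
  ib <- axis_source_index(src$n_bscans, src$dy, tgt$n_bscans, tgt$dy)
  ix <- axis_source_index(src$n_cols, src$dx, tgt$n_cols, tgt$dx)
  out_b <- ib < 0.5 | ib > src$n_bscans + 0.5
  out_x <- ix < 0.5 | ix > src$n_cols + 0.5
  cl <- function(v, n) pmin(pmax(v, 1), n)
  ibc <- cl(ib, src$n_bscans); ixc <- cl(ix, src$n_cols)
  b0 <- pmin(floor(ibc), max(src$n_bscans - 1L, 1L)); fb <- ibc - b0
  x0 <- pmin(floor(ixc), max(src$n_cols - 1L, 1L)); fx <- ixc - x0
  if (src$n_bscans == 1L) { b0 <- rep(1L, length(ibc)); fb <- rep(0, length(ibc)) }
  if (src$n_cols == 1L) { x0 <- rep(1L, length(ixc)); fx <- rep(0, length(ixc)) }
  b1 <- pmin(b0 + 1L, src$n_bscans); x1 <- pmin(x0 + 1L, src$n_cols)
  out <- matrix(NA_real_, tgt$n_bscans, tgt$n_cols)
  B0 <- matrix(b0, tgt$n_bscans, tgt$n_cols); B1 <- matrix(b1, tgt$n_bscans, tgt$n_cols)
  FB <- matrix(fb, tgt$n_bscans, tgt$n_cols)
  X0 <- matrix(x0, tgt$n_bscans, tgt$n_cols, byrow = TRUE)
  X1 <- matrix(x1, tgt$n_bscans, tgt$n_cols, byrow = TRUE)
  FX <- matrix(fx, tgt$n_bscans, tgt$n_cols, byrow = TRUE)
  v00 <- m[cbind(as.vector(B0), as.vector(X0))]
  v01 <- m[cbind(as.vector(B0), as.vector(X1))]
  v10 <- m[cbind(as.vector(B1), as.vector(X0))]
  v11 <- m[cbind(as.vector(B1), as.vector(X1))]
  w00 <- as.vector((1 - FB) * (1 - FX)); w01 <- as.vector((1 - FB) * FX)
  w10 <- as.vector(FB * (1 - FX)); w11 <- as.vector(FB * FX)
  wmat <- cbind(w00, w01, w10, w11)
  vmat <- cbind(v00, v01, v10, v11)
  wmat[is.na(vmat)] <- 0
  vmat[is.na(vmat)] <- 0
  tot <- rowSums(wmat)
  val <- ifelse(tot > 0, rowSums(wmat * vmat) / tot, NA_real_)
  out[] <- val
  out[matrix(out_b, tgt$n_bscans, tgt$n_cols) |
        matrix(out_x, tgt$n_bscans, tgt$n_cols, byrow = TRUE)] <- NA_real_
  out
}

#' Resample one surface map between grids
#'
#' The surface's row positions are converted to physical depth (micrometres,
#' centre-aligned between the two fields of view), interpolated bilinearly
#' over the lateral plane at the target A-scan centres, and converted back to
#' target rows. Bilinear weights of undefined source neighbours are dropped
#' (renormalizing over the defined ones); target columns with no defined
#' neighbour in their footprint, or outside the source lateral extent, become
#' undefined.
#'
#' @param surface numeric matrix `[n_bscans, n_cols]` of row positions on
#'   `source` (`NA` = undefined).
#' @param source,target [grid_spec()] objects with lateral overlap.
#' @return A matrix `[target$n_bscans, target$n_cols]` of target row positions.
#' @export
resample_surface <- function(surface, source, target) {
  stopifnot(is_grid_spec(source), is_grid_spec(target))
  common_fov(source, target)
  if (grids_equal(source, target)) return(surface)
  depth_src <- grid_extent_um(source)[["depth"]]
  depth_tgt <- grid_extent_um(target)[["depth"]]
  z_um <- (surface - 0.5) * source$dz - depth_src / 2  # centred physical depth
  z_t <- interp_surface_lateral(z_um, source, target)
  r <- (z_t + depth_tgt / 2) / target$dz + 0.5
  r[!is.na(r) & (r < 0.5 | r > target$n_rows + 0.5)] <- NA_real_
  r
}

#' Resample a full surface set onto another grid
#'
#' Applies [resample_surface()] to the ILM, RPE and BM maps.
#'
#' @param surfaces an [oct_surfaces()] object.
#' @param target a [grid_spec()].
#' @param check_order passed to [oct_surfaces()].
#' @return An [oct_surfaces()] on `target`.
#' @export
resample_surfaces <- function(surfaces, target, check_order = TRUE) {
  stopifnot(inherits(surfaces, "oct_surfaces"))
  src <- surfaces$grid
  oct_surfaces(
    resample_surface(surfaces$ilm, src, target),
    resample_surface(surfaces$rpe, src, target),
    resample_surface(surfaces$bm, src, target),
    target, check_order = check_order
  )
}
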