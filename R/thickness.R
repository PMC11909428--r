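#' En face RPEDC thickness map
#'
#' Default (mask mode): per-column RPEDC voxel count times the axial spacing,
#' in micrometres, with empty columns undefined. Surface mode:
#' `(bm - rpe) * dz` clamped at zero, undefined where either surface is
#' missing.
#'
#' @param x an [oct_labels()] (mask mode) or [oct_surfaces()] (surface mode).
#' @param grid optional [grid_spec()] override (defaults to `x`'s grid).
#' @return A `thickness_map`: matrix `[n_bscans, n_cols]` of micrometres with
#'   `NA` for undefined columns, plus lateral spacings `dx`, `dy`.
#' @export
rpedc_thickness_map <- function(x, grid = x$grid) {
  stopifnot(is_grid_spec(grid))
  if (inherits(x, "oct_labels")) {
    counts <- apply(x$rpedc, c(2, 3), sum)   # [n_cols, n_bscans]
    map <- t(counts) * grid$dz
    map[map == 0] <- NA_real_
  } else if (inherits(x, "oct_surfaces")) {
    map <- pmax(x$bm - x$rpe, 0) * grid$dz
  } else {
    rlang::abort("rpedc_thickness_map: need oct_labels or oct_surfaces")
  }
  structure(list(map = map, dx = grid$dx, dy = grid$dy),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %d x %d, range [%.1f, %.1f] um, %.1f%% defined\n",
              nrow(x$map), ncol(x$map),
              suppressWarnings(min(x$map, na.rm = TRUE)),
              suppressWarnings(max(x$map, na.rm = TRUE)),
              100 * mean(!is.na(x$map))))
  invisible(x)
}

#' @export
tidy.thickness_map <- function(x, ...) {
  tibble::tibble(
    bscan = rep(seq_len(nrow(x$map)), times = ncol(x$map)),
    col = rep(seq_len(ncol(x$map)), each = nrow(x$map)),
    thickness_um = as.vector(x$map)
  )
}

# Blue-to-red colormap endpoints used by the thickness rendering.
thickness_palette <- c("#00008B", "#0000FF", "#00FFFF", "#FFFF00",
                       "#FF0000", "#8B0000")

#' Render a thickness map to PNG
#'
#' Values are clipped to `[clip_lo, clip_hi]` micrometres (default 0-50) and
#' mapped through a deep-blue-to-deep-red colormap; undefined columns render
#' neutral gray. The image is resized nearest-neighbour so the lateral aspect
#' ratio honours the physical `dx:dy` spacing.
#'
#' @param map a [rpedc_thickness_map()] result.
#' @param path output PNG path.
#' @param clip_lo,clip_hi clipping bounds in micrometres (`clip_hi > clip_lo`).
#' @return `path`, invisibly.
#' @export
render_thickness_png <- function(map, path, clip_lo = 0, clip_hi = 50) {
  stopifnot(inherits(map, "thickness_map"))
  if (clip_hi <= clip_lo) {
    rlang::abort("render_thickness_png: clip_hi must exceed clip_lo")
  }
  m <- pmin(pmax(map$map, clip_lo), clip_hi)
  frac <- (m - clip_lo) / (clip_hi - clip_lo)
  ramp <- grDevices::colorRamp(thickness_palette)
  rgb <- array(0.5, c(nrow(m), ncol(m), 3))  # gray where undefined
  ok <- !is.na(frac)
  if (any(ok)) {
    cols <- ramp(frac[ok]) / 255
    for (c in 1:3) {
      ch <- rgb[, , c]
      ch[ok] <- cols[, c]
      rgb[, , c] <- ch
    }
  }
  # nearest-neighbour resize to physical aspect (rows span dy, cols span dx)
  unit <- min(map$dx, map$dy)
  H <- max(1L, round(nrow(m) * map$dy / unit))
  W <- max(1L, round(ncol(m) * map$dx / unit))
  ri <- pmin(pmax(ceiling(seq_len(H) / H * nrow(m)), 1), nrow(m))
  ci <- pmin(pmax(ceiling(seq_len(W) / W * ncol(m)), 1), ncol(m))
  img <- rgb[ri, ci, , drop = FALSE]
  png::writePNG(img, path)
  invisible(path)
}

#' Plot a thickness map
#'
#' @param object a `thickness_map`.
#' @param clip_lo,clip_hi colour scale bounds in micrometres.
#' @param ... unused.
#' @return A ggplot raster of the en face map.
#' @export
autoplot.thickness_map <- function(object, clip_lo = 0, clip_hi = 50, ...) {
  df <- tidy.thickness_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$bscan,
                                   fill = .data$thickness_um)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = thickness_palette,
                                  limits = c(clip_lo, clip_hi),
                                  oob = scales_squish, na.value = "gray50",
                                  name = "Thickness (um)") +
    ggplot2::coord_fixed(ratio = object$dy / object$dx) +
    ggplot2::labs(x = "A-scan column", y = "B-scan") +
    ggplot2::theme_minimal()
}

# minimal squish (avoids a scales dependency for one helper)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  pmin(pmax(x, range[1]), range[2])
}
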