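#' Write / read an OCT volume as NIfTI
#'
#' Intensities are stored as unsigned 8-bit; voxel spacings go into the NIfTI
#' pixdim header in millimetres (micrometres / 1000). The round trip is
#' lossless for the intensities and reproduces the spacings to header (float)
#' precision.
#'
#' @param vol an [oct_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  g <- vol$grid
  arr <- vol$intensities
  attr(arr, "pixdim") <- c(g$dz, g$dx, g$dy) / 1000
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param device_name device identifier to attach on read.
#' @return For the reader, an [oct_volume()].
#' @export
read_volume_nifti <- function(path, device_name = "unknown") {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)), error = function(e) {
    rlang::abort(sprintf("read_volume_nifti: cannot read '%s': %s", path,
                         conditionMessage(e)))
  })
  d <- dim(img)
  if (length(d) != 3) {
    rlang::abort(sprintf("read_volume_nifti: '%s' is not a 3D volume", path))
  }
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
    rlang::abort(sprintf("read_volume_nifti: '%s' lacks voxel spacings", path))
  }
  grid <- grid_spec(d[1], d[2], d[3], pd[1] * 1000, pd[2] * 1000, pd[3] * 1000)
  oct_volume(array(as.integer(img), d), grid, device_name)
}

#' Write / read label channels as NIfTI masks
#'
#' Each channel goes to its own file `<prefix>_<channel>.nii.gz`.
#'
#' @param labels an [oct_labels()].
#' @param prefix path prefix for the three mask files.
#' @return Named character vector of the three paths.
#' @export
write_labels_nifti <- function(labels, prefix) {
  stopifnot(inherits(labels, "oct_labels"))
  g <- labels$grid
  paths <- character(0)
  for (ch in label_channels) {
    p <- sprintf("%s_%s.nii.gz", prefix, ch)
    arr <- labels[[ch]]
    attr(arr, "pixdim") <- c(g$dz, g$dx, g$dy) / 1000
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), p)
    paths[ch] <- p
  }
  paths
}

#' @rdname write_labels_nifti
#' @return For the reader, an [oct_labels()].
#' @export
read_labels_nifti <- function(prefix) {
  vols <- lapply(label_channels, function(ch) {
    read_volume_nifti(sprintf("%s_%s.nii.gz", prefix, ch))
  })
  oct_labels(vols[[1]]$intensities, vols[[2]]$intensities,
             vols[[3]]$intensities, vols[[1]]$grid)
}

#' Write / read surfaces as CSV
#'
#' Long format with columns `layer`, `bscan`, `col`, `row_px`; undefined
#' positions are encoded as empty fields. Sub-pixel values round-trip exactly
#' (shortest-representation formatting).
#'
#' @param surfaces an [oct_surfaces()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_surfaces_csv <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "oct_surfaces"))
  readr::write_csv(tidy.oct_surfaces(surfaces), path, na = "")
  invisible(path)
}

#' @rdname write_surfaces_csv
#' @param grid the [grid_spec()] the surfaces live on.
#' @param check_order passed to [oct_surfaces()].
#' @return For the reader, an [oct_surfaces()].
#' @export
read_surfaces_csv <- function(path, grid, check_order = TRUE) {
  df <- readr::read_csv(path, col_types = readr::cols(
    layer = readr::col_character(), bscan = readr::col_integer(),
    col = readr::col_integer(), row_px = readr::col_double()
  ), na = "")
  surfaces_from_tidy(df, grid, check_order = check_order)
}

#' Write / read an OCT volume as multipage TIFF
#'
#' One 8-bit page per B-scan. TIFF carries no voxel spacings, so the reader
#' needs the grid. Requires the optional `tiff` package.
#'
#' @param vol an [oct_volume()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    rlang::abort("write_volume_tiff: the 'tiff' package is not installed")
  }
  stopifnot(inherits(vol, "oct_volume"))
  pages <- lapply(seq_len(vol$grid$n_bscans),
                  function(b) vol$intensities[, , b] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param grid the [grid_spec()] of the stored volume.
#' @param device_name device identifier to attach on read.
#' @export
read_volume_tiff <- function(path, grid, device_name = "unknown") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    rlang::abort("read_volume_tiff: the 'tiff' package is not installed")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != grid$n_bscans) {
    rlang::abort(sprintf("read_volume_tiff: '%s' has %d pages, grid expects %d",
                         path, length(pages), grid$n_bscans))
  }
  arr <- array(0L, c(grid$n_rows, grid$n_cols, grid$n_bscans))
  for (b in seq_along(pages)) arr[, , b] <- as.integer(round(pages[[b]] * 255))
  oct_volume(arr, grid, device_name)
}

#' Write a metric table as JSON (and optionally CSV)
#'
#' @param df a data frame of metrics.
#' @param path output `.json` path; a sibling `.csv` is written when
#'   `csv = TRUE`.
#' @param csv also write CSV.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(df, path, csv = TRUE) {
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (csv) readr::write_csv(df, sub("\\.json$", ".csv", path))
  invisible(path)
}
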