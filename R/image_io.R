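#' Multi-channel 3D voxel image
#'
#' Container for a three-channel (CD68, CD163, DAPI) 3D intensity grid
#' with physical voxel spacing in micrometres. All channels share shape;
#' coordinates are physical, origin at the image corner, and the centre of
#' voxel `(i, j, k)` sits at `((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz)`.
#'
#' @param channels named list of 3D numeric arrays (`cd68`, `cd163`, `dapi`).
#' @param spacing_um numeric length-3 voxel spacing (dx, dy, dz) in um.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(channels, spacing_um) {
  stopifnot(is.list(channels), length(channels) >= 1)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) stopf("all channels must be 3D arrays")
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stopf("all channels must share the same shape")
  }
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) || any(spacing_um <= 0)) {
    stopf("spacing_um must be 3 strictly positive numbers")
  }
  structure(list(channels = channels, spacing_um = spacing_um,
                 origin_um = c(0, 0, 0)),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<voxel_image> %d x %d x %d voxels, spacing %s um, channels: %s\n",
              d[1], d[2], d[3], paste(signif(x$spacing_um, 3), collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Physical volume of a voxel image
#' @param image a [voxel_image()].
#' @return Volume in um^3 (voxel count x voxel volume).
#' @export
image_volume_um3 <- function(image) {
  prod(dim(image$channels[[1]])) * prod(image$spacing_um)
}

#' Write / read a voxel image as multi-page TIFF
#'
#' One 32-bit float multi-page TIFF per channel (`<prefix>_<channel>.tif`,
#' one page per z-slice) plus a JSON sidecar (`<prefix>_meta.json`) holding
#' voxel spacing, channel names and grid shape.
#'
#' @param image a [voxel_image()].
#' @param prefix path prefix for the output files.
#' @return `write_voxel_image` returns the sidecar path invisibly;
#'   `read_voxel_image` returns the reconstructed [voxel_image()].
#' @export
write_voxel_image <- function(image, prefix) {
  stopifnot(inherits(image, "voxel_image"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  scale <- max(1, max(vapply(image$channels, max, 1.0)))
  for (ch in names(image$channels)) {
    a <- image$channels[[ch]] / scale  # tiff stores floats in [0, 1]
    pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k])
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", prefix, ch),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  meta <- list(spacing_um = image$spacing_um,
               channels = names(image$channels),
               dim = dim(image$channels[[1]]),
               intensity_scale = scale)
  path <- sprintf("%s_meta.json", prefix)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_voxel_image
#' @export
read_voxel_image <- function(prefix) {
  meta_path <- sprintf("%s_meta.json", prefix)
  if (!file.exists(meta_path)) stopf("no image metadata at '%s'", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  channels <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, ch), all = TRUE)
    a <- array(0, dim = meta$dim)
    for (k in seq_along(pages)) a[, , k] <- pages[[k]]
    channels[[ch]] <- a * (meta$intensity_scale %||% 1)
  }
  voxel_image(channels, meta$spacing_um)
}
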