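# Image and annotation I/O.
#
# Images are height x width x 3 integer arrays (0-255). Label maps are stored
# on disk as 16-bit grayscale TIFF (lossless for up to 65535 ids); annotation
# masks are accepted as PNG or TIFF, binary or already-labelled.

#' Read an RGB image
#'
#' Reads a PNG or TIFF image and returns a height x width x 3 array of
#' integer channel values in 0-255. Grayscale input is replicated across
#' channels; an alpha channel, if present, is dropped (but see
#' [load_annotation()] which uses it for masks).
#'
#' @param path file path; format inferred from the extension.
#' @return height x width x 3 integer array.
#' @export
load_image <- function(path) {
  arr <- read_image_array(path)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  k <- dim(arr)[3]
  rgb <- if (k >= 3L) arr[, , 1:3, drop = FALSE] else arr[, , c(1L, 1L, 1L), drop = FALSE]
  storage.mode(rgb) <- "integer"
  rgb
}

# raw decode: returns 2D matrix or 3D array of integers 0-255 (alpha kept),
# plus attr "bits" and attr "raw01" (the original 0-1 values at full depth)
read_image_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (expected png/tif/tiff): ", path))
  out <- round(x * 255)
  storage.mode(out) <- "integer"
  attr(out, "raw01") <- x
  out
}

#' Write an RGB image as PNG
#'
#' @param image height x width x 3 integer array (0-255).
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  png::writePNG(array(pmin(pmax(image, 0L), 255L) / 255, dim(image)), path)
  invisible(path)
}

#' Write a label map to disk
#'
#' Stores the map as a single-channel 16-bit grayscale TIFF, which round-trips
#' ids 0-65535 losslessly.
#'
#' @param map label map (integer matrix); at most 65535 instances.
#' @param path output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
save_labelmap <- function(map, path) {
  validate_labelmap(map)
  if (max(map) > 65535L)
    stop("label map has ", max(map), " ids; 16-bit storage caps at 65535")
  tiff::writeTIFF(map / 65535, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a ground-truth or prediction annotation
#'
#' Two dialects are supported. `kind = "binary_mask"`: any pixel with nonzero
#' alpha (when an alpha channel is present, as produced by drawing lumina on a
#' transparent layer) or, otherwise, nonzero luminance is foreground; the mask
#' is then split into connected components. `kind = "label_map"`: a
#' single-channel 16-bit file whose pixel values are instance ids verbatim;
#' ids are renumbered to 1..N preserving geometry.
#'
#' @param path PNG or TIFF file.
#' @param kind `"binary_mask"` or `"label_map"`.
#' @param connectivity 4 or 8; used only for `binary_mask`.
#' @return normalized label map.
#' @export
load_annotation <- function(path, kind = c("binary_mask", "label_map"),
                            connectivity = 8) {
  kind <- match.arg(kind)
  arr <- read_image_array(path)
  raw01 <- attr(arr, "raw01")
  if (kind == "label_map") {
    if (length(dim(arr)) == 3L && dim(arr)[3] > 1L)
      stop("label_map annotation must be single-channel; '", path,
           "' has ", dim(arr)[3], " channels")
    m <- if (length(dim(raw01)) == 3L) raw01[, , 1] else raw01
    ids <- round(m * 65535)
    storage.mode(ids) <- "integer"
    return(normalize_labels(ids))
  }
  # binary mask: alpha wins when present
  if (length(dim(arr)) == 3L && dim(arr)[3] %in% c(2L, 4L)) {
    fg <- arr[, , dim(arr)[3]] > 0L
  } else if (length(dim(arr)) == 3L) {
    lum <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    fg <- lum > 0
  } else {
    fg <- arr > 0L
  }
  binary_mask_to_labelmap(fg, connectivity = connectivity)
}

#' Read a stored label map
#'
#' Companion to [save_labelmap()]; equivalent to
#' `load_annotation(path, kind = "label_map")`.
#'
#' @param path 16-bit grayscale TIFF (or PNG) written by [save_labelmap()].
#' @return normalized label map.
#' @export
load_labelmap <- function(path) load_annotation(path, kind = "label_map")
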