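#' Read an 8-bit RGB image
#'
#' Reads a PNG or TIFF file as an H x W x 3 array of 8-bit values (0-255).
#' Grayscale files are replicated across the three channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path file path (.png, .tif or .tiff).
#' @return H x W x 3 numeric array with integer values in \[0, 255\].
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    img <- img * 255
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    img <- img * 255
  } else {
    stop("unsupported image format '", ext, "' (expected png/tif/tiff): ", path)
  }
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2L) img <- array(img[, , 1], c(dim(img)[1:2], 3L))
  round(img)
}

#' Write an 8-bit RGB image as PNG
#'
#' @param rgb H x W x 3 array of values in \[0, 255\].
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(rgb, path) {
  rgb <- as_rgb_array(rgb)
  png::writePNG(clip01(rgb / 255), path)
  invisible(path)
}

#' Load a nucleus instance mask from file
#'
#' Reads a single-channel integer label raster (0 = background, k >= 1 =
#' nucleus k) from an 8- or 16-bit PNG, or an integer TIFF. Labels are
#' returned exactly as stored; no relabeling or postprocessing is applied.
#'
#' @param path file path (.png, .tif, .tiff).
#' @return Integer matrix of labels.
#' @export
load_instance_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) == 3L)
      stop("instance mask must be single-channel; '", basename(path),
           "' has ", dim(img)[3], " channels")
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    labels <- round(img * (2^depth - 1))
  } else if (ext %in% c("tif", "tiff")) {
    probe <- tiff::readTIFF(path, info = TRUE)
    if (length(dim(probe)) == 3L)
      stop("instance mask must be single-channel; '", basename(path),
           "' has ", dim(probe)[3], " channels")
    if (isTRUE(attr(probe, "bits.per.sample") >= 32L))
      stop("instance mask must be an integer raster; '", basename(path),
           "' stores floating-point samples")
    labels <- round(tiff::readTIFF(path, as.is = TRUE))
  } else {
    stop("unsupported mask format '", ext, "' (expected png/tif/tiff): ", path)
  }
  if (any(labels < 0))
    stop("instance mask labels must be non-negative")
  storage.mode(labels) <- "integer"
  labels
}

#' Write a nucleus instance mask to a 16-bit TIFF
#'
#' @param labels integer label matrix (values in \[0, 65535\]).
#' @param path output path (.tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_instance_mask <- function(labels, path) {
  labels <- as.matrix(labels)
  if (any(labels < 0) || max(labels) > 65535)
    stop("labels must lie in [0, 65535] for 16-bit output")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
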