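#' Construct a calibrated smear image
#'
#' A `smear_image` bundles an 8-bit RGB pixel grid with the physical
#' calibration (micrometers per pixel) that every downstream area
#' computation depends on. Fields of view are expected at 1000x (oil
#' immersion) magnification, where a typical camera yields on the order of
#' 0.1 um/px.
#'
#' @param pixels numeric array `height x width x 3`, channel values in
#'   `[0, 255]` (R, G, B).
#' @param microns_per_pixel physical side length of one pixel in
#'   micrometers; must be finite and strictly positive.
#' @param source_id character label identifying the field of view.
#'
#' @return An object of class `smear_image`: a list with elements
#'   `pixels`, `microns_per_pixel`, `source_id`.
#' @export
smear_image <- function(pixels, microns_per_pixel, source_id = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a height x width x 3 RGB array")
  d <- dim(pixels)
  if (d[1] < 64L || d[2] < 64L)
    stop("image must be at least 64 x 64 pixels, got ", d[1], " x ", d[2])
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("`microns_per_pixel` must be a finite, strictly positive scalar")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  structure(
    list(pixels = pixels, microns_per_pixel = microns_per_pixel,
         source_id = as.character(source_id)),
    class = "smear_image"
  )
}

#' @export
print.smear_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<smear_image> %d x %d px, %.4g um/px (%s x %s um), source '%s'\n",
              d[1], d[2], x$microns_per_pixel,
              format(d[1] * x$microns_per_pixel),
              format(d[2] * x$microns_per_pixel), x$source_id))
  invisible(x)
}

#' Read a smear image from disk
#'
#' Reads an 8-bit RGB PNG or TIFF micrograph and attaches its spatial
#' calibration. An alpha channel, if present, is dropped; grayscale or
#' otherwise non-RGB files are rejected.
#'
#' @param path path to a PNG or TIFF file.
#' @param microns_per_pixel calibration, um/px.
#' @param source_id label for the image; defaults to the file name.
#' @return A [smear_image].
#' @export
load_image <- function(path, microns_per_pixel,
                       source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      # unknown extension: try both decoders before giving up
      tryCatch(png::readPNG(path), error = function(e) tiff::readTIFF(path))
    ),
    error = function(e) stop("cannot decode '", path, "' as PNG or TIFF: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.matrix(raw)) stop("'", path, "' is a single-channel image; RGB required")
  if (length(dim(raw)) != 3L || !dim(raw)[3] %in% c(3L, 4L))
    stop("'", path, "' does not decode to a 3-channel RGB image")
  smear_image(raw[, , 1:3, drop = FALSE] * 255, microns_per_pixel, source_id)
}

#' Write a smear image to a PNG file
#'
#' @param img a [smear_image].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "smear_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' Convert an RGB smear image to HSV
#'
#' Standard hexcone conversion, applied per pixel. Hue is reported in
#' degrees `[0, 360)`; saturation and value in `[0, 1]`. Segmentation runs
#' on the saturation channel: stained cells are strongly saturated while
#' the smear background is pale.
#'
#' @param img a [smear_image].
#' @return An object of class `hsv_image`: list of matrices `h`, `s`, `v`
#'   with the source dimensions.
#' @export
rgb_to_hsv <- function(img) {
  stopifnot(inherits(img, "smear_image"))
  d <- dim(img$pixels)
  m <- rbind(as.vector(img$pixels[, , 1]),
             as.vector(img$pixels[, , 2]),
             as.vector(img$pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  shape <- function(v) matrix(v, d[1], d[2])
  structure(
    list(h = shape(hsv[1, ] * 360) %% 360, s = shape(hsv[2, ]),
         v = shape(hsv[3, ])),
    class = "hsv_image"
  )
}

#' Convert an RGB smear image to grayscale
#'
#' Luminance conversion with ITU-R BT.601 weights,
#' `0.299 R + 0.587 G + 0.114 B`. This gray representation underlies the
#' per-cell mean gray value G and the image-wide mean Mg used to separate
#' RBCs from nucleated cells.
#'
#' @param img a [smear_image].
#' @return A numeric matrix of intensities in `[0, 255]`.
#' @export
rgb_to_gray <- function(img) {
  stopifnot(inherits(img, "smear_image"))
  0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] +
    0.114 * img$pixels[, , 3]
}

#' Convert a pixel area to square micrometers
#'
#' @param area_px area in pixels (>= 0).
#' @param microns_per_pixel calibration, um/px.
#' @return `area_px * microns_per_pixel^2`, in um^2.
#' @export
px_area_to_um2 <- function(area_px, microns_per_pixel) {
  if (any(area_px < 0)) stop("pixel area must be non-negative")
  if (!is.numeric(microns_per_pixel) || any(!is.finite(microns_per_pixel)) ||
      any(microns_per_pixel <= 0))
    stop("`microns_per_pixel` must be finite and strictly positive")
  area_px * microns_per_pixel^2
}
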