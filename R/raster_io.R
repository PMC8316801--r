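## Raster input and the pixel/unit-square coordinate conventions.
##
## A pixel field stores one scalar intensity in [0, 1] per pixel; by default
## intensity is inverted luminance so that a dark subject on a light
## background gets high values, which the transport dynamics treat as high
## initial conductivity. Pixel (row r, col c) has centre
## x = (c - 0.5)/W, y = 1 - (r - 0.5)/H, i.e. the image is rescaled to the
## unit square with y increasing upward.

#' Construct a pixel field
#'
#' A `pixel_field` is an image reduced to a matrix of scalar intensities in
#' \[0, 1\] (rows are image rows, top to bottom), plus the geometry metadata
#' needed to map pixels to unit-square coordinates.
#'
#' @param intensity Numeric matrix of per-pixel intensities in \[0, 1\].
#' @return An object of class `pixel_field` with elements `intensity`,
#'   `height`, `width` and `origin`.
#' @examples
#' f <- pixel_field(matrix(c(0.2, 0.9, 0.4, 0.1), 2, 2))
#' f$height
#' @export
pixel_field <- function(intensity) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop_validation("intensity must be a numeric matrix")
  if (nrow(intensity) < 1 || ncol(intensity) < 1)
    stop_validation("pixel field must be at least 1x1")
  if (any(!is.finite(intensity)))
    stop_validation("intensities must be finite")
  if (any(intensity < 0 | intensity > 1))
    stop_validation("intensities must lie in [0, 1]")
  structure(
    list(intensity = intensity,
         height = nrow(intensity),
         width = ncol(intensity),
         origin = "top-left rows; centres x=(c-0.5)/W, y=1-(r-0.5)/H"),
    class = "pixel_field")
}

#' @export
print.pixel_field <- function(x, ...) {
  cat(sprintf("pixel_field: %d x %d, intensity in [%.3f, %.3f]\n",
              x$height, x$width, min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Map colour values to scalar intensity
#'
#' Monotone mapping from colour to a conductivity-like intensity in
#' \[0, 1\]. The default mode, `"luminance_inverted"`, assigns high intensity
#' to dark pixels (network subjects are typically dark strokes on a light
#' background). Normalisation divides by the theoretical channel maximum
#' (`maxval`), never the observed one.
#'
#' @param rgb A height x width x channels array, or a plain matrix/vector of
#'   grey values. Channel values must lie in \[0, `maxval`\].
#' @param mode One of `"luminance_inverted"`, `"luminance"`, or
#'   `"channel:k"` for an integer channel index k.
#' @param maxval Theoretical channel maximum (255 for 8-bit integer input,
#'   1 for already-normalised input).
#' @return Matrix (or vector, matching the input shape) of intensities in
#'   \[0, 1\].
#' @examples
#' to_intensity(c(0, 0, 0))            # 1: darkest pixel
#' to_intensity(c(255, 255, 255))      # 0: brightest pixel
#' @export
to_intensity <- function(rgb, mode = "luminance_inverted", maxval = 255) {
  if (any(!is.finite(rgb)))
    stop_validation("colour values must be finite")
  if (any(rgb < 0 | rgb > maxval))
    stop_validation("colour values must lie in [0, %s]", format(maxval))
  v <- rgb / maxval
  grey <- if (is.array(v) && length(dim(v)) == 3) {
    nch <- dim(v)[3]
    if (startsWith(mode, "channel:")) {
      k <- suppressWarnings(as.integer(sub("^channel:", "", mode)))
      if (is.na(k) || k < 1 || k > nch)
        stop_config("unknown channel in intensity mode '%s'", mode)
      v[, , k]
    } else if (nch >= 3) {
      0.2126 * v[, , 1] + 0.7152 * v[, , 2] + 0.0722 * v[, , 3]
    } else {
      v[, , 1]
    }
  } else {
    if (startsWith(mode, "channel:")) v
    else if (is.null(dim(v)) && length(v) == 3) {
      ## a single colour triplet
      sum(c(0.2126, 0.7152, 0.0722) * v)
    } else v
  }
  out <- switch(
    sub(":.*$", "", mode),
    luminance_inverted = 1 - grey,
    luminance = grey,
    channel = grey,
    stop_config("unknown intensity mode '%s'", mode))
  pmin(pmax(out, 0), 1)
}

#' Threshold a pixel field
#'
#' Boolean mask of pixels whose intensity strictly exceeds `delta`; these are
#' the pixels that contribute to the network-like subject.
#'
#' @param field A [pixel_field].
#' @param delta Threshold in \[0, 1\].
#' @return Logical matrix of the field's dimensions.
#' @export
threshold_mask <- function(field, delta) {
  stopifnot(inherits(field, "pixel_field"))
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta > 1)
    stop_validation("delta must be a scalar in [0, 1], got %s",
                    format(delta))
  field$intensity > delta
}

#' Load an image as a pixel field
#'
#' Reads a PNG, TIFF or JPEG image, maps colour to intensity with
#' [to_intensity], and optionally applies a Gaussian blur and a linear
#' contrast stretch (a deliberately small, configurable stand-in for heavier
#' pre-processing pipelines).
#'
#' @param path Path to a readable PNG/TIFF/JPEG file.
#' @param intensity_mode Passed to [to_intensity].
#' @param blur_sigma Gaussian blur standard deviation in pixels; 0 disables.
#' @param contrast_stretch If `TRUE`, linearly rescale intensities to span
#'   \[0, 1\].
#' @return A [pixel_field].
#' @export
load_image <- function(path, intensity_mode = "luminance_inverted",
                       blur_sigma = 0, contrast_stretch = FALSE) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop_io("cannot read image file '%s'", as.character(path)[1])
  ext <- tolower(tools::file_ext(path))
  arr <- switch(
    ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img)   # (x, y[, ch]) order
      if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else t(a)
    },
    stop_io("unsupported image format '.%s' (need PNG/TIFF/JPEG)", ext))
  if (length(arr) == 0)
    stop_validation("zero-size image '%s'", path)
  inten <- to_intensity(arr, mode = intensity_mode, maxval = 1)
  if (!is.matrix(inten)) inten <- matrix(inten, nrow = dim(arr)[1])
  if (blur_sigma > 0)
    inten <- gaussian_blur(inten, blur_sigma)
  if (isTRUE(contrast_stretch)) {
    rng <- range(inten)
    if (diff(rng) > 0) inten <- (inten - rng[1]) / diff(rng)
  }
  pixel_field(pmin(pmax(inten, 0), 1))
}

gaussian_blur <- function(m, sigma) {
  b <- EBImage::gblur(t(m), sigma = sigma)
  pmin(pmax(t(as.matrix(b)), 0), 1)
}

#' Write a pixel field as a greyscale PNG
#'
#' Writes `1 - intensity` as 8-bit grey so that reading the file back with
#' the default inverted-luminance mapping round-trips intensities to within
#' 1/255.
#'
#' @param field A [pixel_field].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_image <- function(field, path) {
  stopifnot(inherits(field, "pixel_field"))
  png::writePNG(1 - field$intensity, target = path)
  invisible(path)
}
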