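#' Grayscale image container
#'
#' Wraps a 2D intensity matrix together with its provenance: working bit
#' depth, zoom state, the interpolation kernel that produced it, and a
#' source-resolution tag. All intensities are stored as base-R numerics in
#' `[0, 2^bit_depth - 1]`; the working depth throughout the package is 8 bit.
#'
#' Coordinate convention (used everywhere in the package): pixels are indexed
#' 0-based, row-major; rectangles are half-open, i.e. a [ROIRect] with
#' `row0, col0, height, width` covers rows `row0 .. row0 + height - 1`.
#'
#' @param pixels numeric matrix of intensities.
#' @param bit_depth working bit depth; intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param zoom_state `"native"` or `"zoomed"`.
#' @param zoom_factor linear magnification factor (1 for native images).
#' @param kernel interpolation kernel that produced the image:
#'   `"none"`, `"nearest"`, `"bilinear"` or `"bicubic"`.
#' @param source_resolution_tag one of `"1023x496"`, `"1023x593"`,
#'   `"synthetic"`, `"other"`.
#' @return An object of class `grayscale_image`.
#' @export
grayscale_image <- function(pixels, bit_depth = 8L, zoom_state = "native",
                            zoom_factor = 1, kernel = "none",
                            source_resolution_tag = "other") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("'pixels' must be a non-empty matrix", call. = FALSE)
  storage.mode(pixels) <- "double"
  maxval <- 2^bit_depth - 1
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > maxval))
    stop("intensities must be finite and within [0, ", maxval, "]",
         call. = FALSE)
  zoom_state <- match.arg(zoom_state, c("native", "zoomed"))
  kernel <- match.arg(kernel, c("none", "nearest", "bilinear", "bicubic"))
  source_resolution_tag <- match.arg(
    source_resolution_tag, c("1023x496", "1023x593", "synthetic", "other"))
  if (zoom_factor < 1) stop("'zoom_factor' must be >= 1", call. = FALSE)
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         zoom_state = zoom_state, zoom_factor = zoom_factor,
         kernel = kernel, source_resolution_tag = source_resolution_tag),
    class = "grayscale_image")
}

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("<grayscale_image> %d x %d, %d-bit, %s (factor %.3g, kernel %s), source %s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$zoom_state,
              x$zoom_factor, x$kernel, x$source_resolution_tag))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.grayscale_image <- function(x) dim(x$pixels)

#' Rectangular region of interest
#'
#' 0-based, half-open rectangle: rows `row0 .. row0 + height - 1`, columns
#' `col0 .. col0 + width - 1`.
#'
#' @param row0,col0 0-based indices of the top-left pixel.
#' @param height,width extent in pixels (>= 1).
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(row0, col0, height, width) {
  if (height < 1 || width < 1)
    stop("ROI height and width must be >= 1", call. = FALSE)
  if (row0 < 0 || col0 < 0)
    stop("ROI origin must be non-negative", call. = FALSE)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("<roi_rect> origin (%d, %d), %d x %d\n",
              x$row0, x$col0, x$height, x$width))
  invisible(x)
}

#' Crop a region of interest out of an image
#'
#' Values are copied; provenance fields (bit depth, zoom state, factor,
#' kernel, source tag) are preserved.
#'
#' @param img a [grayscale_image].
#' @param rect a [roi_rect], fully inside `img`.
#' @return A [grayscale_image] of shape `height x width`.
#' @export
crop_roi <- function(img, rect) {
  stopifnot(inherits(img, "grayscale_image"), inherits(rect, "roi_rect"))
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (rect$row0 + rect$height > nr || rect$col0 + rect$width > nc)
    stop(sprintf("ROI [%d+%d, %d+%d] exceeds image bounds %d x %d",
                 rect$row0, rect$height, rect$col0, rect$width, nr, nc),
         call. = FALSE)
  sub <- img$pixels[(rect$row0 + 1L):(rect$row0 + rect$height),
                    (rect$col0 + 1L):(rect$col0 + rect$width), drop = FALSE]
  out <- img
  out$pixels <- sub
  out
}

#' Total pixel count of an image or ROI
#'
#' The number of pixels in the analyzed region, `height * width`. Inflates
#' under digital zoom (by exactly `factor^2` for integer nearest-neighbour
#' zoom) without adding anatomical information.
#'
#' @param img a [grayscale_image].
#' @return Integer pixel count.
#' @export
pixel_count <- function(img) {
  stopifnot(inherits(img, "grayscale_image"))
  nrow(img$pixels) * ncol(img$pixels)
}
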