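#' Read a grayscale radiograph
#'
#' Reads a single-frame grayscale image from DICOM, PNG or TIFF and maps it
#' to the 8-bit working depth. When the stored depth exceeds 8 bits the
#' intensities are min-max rescaled to `[0, 255]` with round-half-to-even
#' (the deterministic, window-free conversion): `round(255 * (v - min) /
#' (max - min))`; a constant image maps to 0. Color or multi-frame payloads
#' are rejected.
#'
#' @param path path to the image file.
#' @param format `"DICOM"`, `"PNG"` or `"TIFF"`; guessed from the file
#'   extension when omitted.
#' @param source_resolution_tag provenance tag recorded on the result.
#' @return A [grayscale_image] with `zoom_state = "native"`.
#' @export
read_image <- function(path, format = c("auto", "DICOM", "PNG", "TIFF"),
                       source_resolution_tag = "other") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      dcm = "DICOM", dicom = "DICOM", png = "PNG",
      tif = "TIFF", tiff = "TIFF",
      stop("cannot guess format from extension '", ext, "'", call. = FALSE))
  }
  raw_img <- switch(format,
    PNG  = read_png_gray(path),
    TIFF = read_tiff_gray(path),
    DICOM = read_dicom_gray(path))
  m <- rescale_to_8bit(raw_img$values, raw_img$stored_bits)
  grayscale_image(m, bit_depth = 8L, zoom_state = "native",
                  source_resolution_tag = source_resolution_tag)
}

# png/tiff packages return arrays in [0, 1]; recover integer sample values.
read_png_gray <- function(path) {
  a <- png::readPNG(path, info = TRUE)
  bits <- attr(a, "info")$bit.depth
  if (is.null(bits)) bits <- 8L
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] %in% c(2L, 4L)) a <- a[, , -dim(a)[3], drop = FALSE]  # drop alpha
    if (length(dim(a)) == 3L && dim(a)[3] > 1L) {
      chans <- apply(a, 3, identity, simplify = FALSE)
      if (!all(vapply(chans[-1], function(ch) isTRUE(all.equal(ch, chans[[1]])),
                      logical(1))))
        stop("color PNG without a grayscale reduction rule", call. = FALSE)
    }
    a <- a[, , 1]
  }
  list(values = strip_attrs(round(a * (2^bits - 1))),
       stored_bits = as.integer(bits))
}

read_tiff_gray <- function(path) {
  a <- tiff::readTIFF(path, info = TRUE, all = FALSE)
  bits <- attr(a, "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] > 1L &&
        !all(apply(a, 3, function(ch) isTRUE(all.equal(ch, a[, , 1])))))
      stop("color TIFF without a grayscale reduction rule", call. = FALSE)
    a <- a[, , 1]
  }
  list(values = strip_attrs(round(a * (2^bits - 1))),
       stored_bits = as.integer(bits))
}

strip_attrs <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# Min-max rescale deeper-than-8-bit data to [0, 255]; base round() is
# round-half-to-even. 8-bit (or shallower) data passes through unchanged.
rescale_to_8bit <- function(v, stored_bits) {
  if (stored_bits <= 8L) return(v)
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(matrix(0, nrow(v), ncol(v)))
  round(255 * (v - lo) / (hi - lo))
}

#' Write a matrix or image as 8-bit grayscale PNG
#'
#' Depth maps and other non-intensity matrices are linearly rescaled to the
#' full 8-bit range before writing; intensity images in `[0, 255]` are
#' written as-is.
#'
#' @param x a [grayscale_image] or numeric matrix.
#' @param path output path.
#' @param rescale linearly map `[min, max]` to `[0, 255]` before writing
#'   (the default for bare matrices; ignored range when constant).
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path, rescale = !inherits(x, "grayscale_image")) {
  m <- if (inherits(x, "grayscale_image")) x$pixels else x
  if (rescale) {
    lo <- min(m); hi <- max(m)
    m <- if (hi > lo) (m - lo) / (hi - lo) * 255 else m * 0
  }
  png::writePNG(round(m) / 255, target = path)
  invisible(path)
}
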