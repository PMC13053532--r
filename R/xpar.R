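#' Transmittance depth map of an ROI
#'
#' For each row `i` of the ROI let `Ai` be the row maximum (the brightest,
#' most attenuating pixel in that row, used as the row's transmittance
#' reference) and `Bij` the gray level at `(i, j)`. The per-pixel depth
#' value is
#' \deqn{R_{ij} = [\log((A_i - B_{ij})^2 + 1) \cdot
#'                \sin(\tfrac{\pi}{2} B_{ij}/A_i)]^2}
#' with the natural logarithm by default (the base only rescales the map;
#' it is configurable). The map models X-ray transmittance through
#' mineralized tissue: pixels far below their row reference (deep, less
#' mineralized structure such as the pulp canal) score high, while pixels
#' at the reference (`Bij = Ai`) and fully dark pixels (`Bij = 0`, sine
#' factor zero) score zero. Rows with `Ai = 0` carry no transmittance
#' signal and are defined as all-zero.
#'
#' The row reference is ROI-local: `Ai` is the maximum within the cropped
#' ROI row, not within the full radiograph row.
#'
#' @param roi a [grayscale_image] or numeric matrix (the cropped ROI).
#' @param log_base base of the logarithm (default `exp(1)`).
#' @return An object of class `depth_map`: list with `r_values` (matrix of
#'   `Rij`, same shape as the ROI), `row_max` (vector of `Ai`) and
#'   `log_base`.
#' @export
depth_map <- function(roi, log_base = exp(1)) {
  m <- if (inherits(roi, "grayscale_image")) roi$pixels else roi
  if (!is.matrix(m) || length(m) == 0L)
    stop("ROI is empty", call. = FALSE)
  a <- apply(m, 1, max)
  a_safe <- ifelse(a > 0, a, 1)              # rows with Ai = 0 zeroed below
  d <- m - a                                  # Bij - Ai (<= 0)
  r <- (log(d^2 + 1, base = log_base) * sin(pi / 2 * m / a_safe))^2
  r[a == 0, ] <- 0
  structure(list(r_values = r, row_max = a, log_base = log_base),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %d x %d, log base %.4g\n",
              nrow(x$r_values), ncol(x$r_values), x$log_base))
  cat(sprintf("  Rij range [%.4g, %.4g], mean %.4g\n",
              min(x$r_values), max(x$r_values), mean(x$r_values)))
  invisible(x)
}

#' Xpar depth index
#'
#' Scalar summary of the depth map: the arithmetic mean of all `Rij` over
#' the ROI, expressing the relative depth variation per pixel. Zero exactly
#' when the map is all-zero (e.g. a constant ROI).
#'
#' @param dm a [depth_map].
#' @return Non-negative scalar.
#' @export
xpar_index <- function(dm) {
  stopifnot(inherits(dm, "depth_map"))
  mean(dm$r_values)
}

#' Power Xpar depth index
#'
#' Amplified depth index emphasizing the large `Rij` values of the ROI:
#' a scaled generalized power mean,
#' \deqn{\mathrm{PowerXpar} = s \cdot \left(\frac{1}{N}\sum R_{ij}^p\right)^{1/p}}
#' with defaults `p = 2`, `s = 10`. For `p > 1` heavy upper tails of the
#' depth distribution (focal deep structure such as a complex canal) raise
#' the index faster than the plain mean; the index is monotone in every
#' `Rij` and equals `s * c` on a constant map `Rij = c`.
#'
#' @param dm a [depth_map].
#' @param p power-mean exponent, `>= 1`.
#' @param scale positive multiplier.
#' @return Non-negative scalar.
#' @export
power_xpar_index <- function(dm, p = 2, scale = 10) {
  stopifnot(inherits(dm, "depth_map"))
  if (p < 1) stop("'p' must be >= 1", call. = FALSE)
  if (scale <= 0) stop("'scale' must be > 0", call. = FALSE)
  scale * mean(dm$r_values^p)^(1 / p)
}

#' Texture metric bundle for one viewing condition
#'
#' @param roi a [grayscale_image] ROI.
#' @param condition `"non_zoomed"` or `"zoomed"`.
#' @param power_p,power_scale settings of [power_xpar_index()].
#' @param log_base depth-map logarithm base.
#' @return An object of class `texture_metrics`: `xpar`, `power_xpar`,
#'   `pixel_count`, `condition`, `power_p`, `power_scale`.
#' @export
texture_metrics <- function(roi, condition = c("non_zoomed", "zoomed"),
                            power_p = 2, power_scale = 10,
                            log_base = exp(1)) {
  condition <- match.arg(condition)
  dm <- depth_map(roi, log_base = log_base)
  structure(
    list(xpar = xpar_index(dm),
         power_xpar = power_xpar_index(dm, p = power_p, scale = power_scale),
         pixel_count = pixel_count(roi),
         condition = condition, power_p = power_p, power_scale = power_scale),
    class = "texture_metrics")
}

#' @export
print.texture_metrics <- function(x, ...) {
  cat(sprintf("<texture_metrics> [%s] Xpar %.3f, Power Xpar %.3f (p = %g, scale = %g), Pixel Count %d\n",
              x$condition, x$xpar, x$power_xpar, x$power_p, x$power_scale,
              x$pixel_count))
  invisible(x)
}

#' Paired non-zoomed / zoomed metric bundles for an ROI
#'
#' Computes the three indices on the native ROI and again after digital
#' magnification of the same ROI, mirroring how an operator records both
#' viewing conditions. With `zoom_factor = 1` the two bundles are identical
#' up to the condition tag; with integer-factor nearest-neighbour zoom the
#' Xpar indices are preserved exactly (pixel duplication keeps the per-row
#' value multiset and row maxima) while Pixel Count scales by `factor^2`.
#'
#' @param roi a [grayscale_image] ROI.
#' @param zoom_factor linear magnification, `>= 1`.
#' @param kernel interpolation kernel for [digital_zoom()].
#' @param power_p,power_scale,log_base index settings.
#' @return List with elements `non_zoomed` and `zoomed`, each a
#'   `texture_metrics`.
#' @export
metrics_bundle <- function(roi, zoom_factor = 1.25, kernel = "bilinear",
                           power_p = 2, power_scale = 10,
                           log_base = exp(1)) {
  nz <- texture_metrics(roi, "non_zoomed", power_p, power_scale, log_base)
  zroi <- digital_zoom(roi, zoom_factor, kernel)
  z <- texture_metrics(zroi, "zoomed", power_p, power_scale, log_base)
  list(non_zoomed = nz, zoomed = z)
}

#' Export a depth map
#'
#' Writes the `Rij` matrix either as a CSV matrix (exact values) or as a
#' linearly rescaled 8-bit PNG for visual inspection.
#'
#' @param dm a [depth_map].
#' @param path output path; format chosen by extension (`.csv` or `.png`).
#' @return `path`, invisibly.
#' @export
export_depth_map <- function(dm, path) {
  stopifnot(inherits(dm, "depth_map"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(dm$r_values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext == "png") {
    write_image_png(dm$r_values, path, rescale = TRUE)
  } else stop("unsupported depth-map export format '.", ext, "'",
              call. = FALSE)
  invisible(path)
}
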