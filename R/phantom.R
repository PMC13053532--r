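#' Parameters of a synthetic dentin-pulp ROI phantom
#'
#' Describes a rectangular ROI emulating the cropped dentin-pulp complex of
#' a mandibular premolar on a panoramic radiograph: a bright, smoothly
#' graded dentin body with a darker root-canal region running through it,
#' softened by blur and corrupted by acquisition noise.
#'
#' The canal is rendered either as a narrow axis-aligned ellipse
#' (`"simple"`, an ordinary single canal) or as a curved ribbon arc
#' (`"c_shaped"`, the ribbon-like morphology left by incomplete root-sheath
#' fusion). Both shapes share the same ribbon thickness (`canal_width`) and
#' the same area budget, so they differ in arrangement, not in total dark
#' area - the C-shape's arc radius is solved from the area budget.
#'
#' @param roi_height,roi_width ROI extent in pixels (>= 8).
#' @param dentin_mean mean dentin intensity (0-255).
#' @param dentin_gradient intensity change per pixel along the root axis
#'   (down rows); within-row it is constant so the row-referenced depth map
#'   is unaffected.
#' @param canal_shape `"simple"` or `"c_shaped"`.
#' @param canal_contrast intensity drop of the canal below the dentin body,
#'   `0 < canal_contrast <= dentin_mean` (0 disables the canal).
#' @param canal_width ribbon thickness in pixels.
#' @param c_arc_span angular span of the C-shaped arc, radians.
#' @param noise_sd additive white Gaussian noise SD, intensity units.
#' @param blur_sigma Gaussian blur of the structure field, pixels.
#' @param bit_depth working bit depth (8).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(roi_height = 50, roi_width = 40,
                           dentin_mean = 180, dentin_gradient = 0.2,
                           canal_shape = c("simple", "c_shaped"),
                           canal_contrast = 32, canal_width = 6,
                           c_arc_span = 3.5, noise_sd = 2.5,
                           blur_sigma = 1, bit_depth = 8L) {
  canal_shape <- match.arg(canal_shape)
  if (roi_height < 8 || roi_width < 8)
    stop("ROI must be at least 8 x 8 pixels", call. = FALSE)
  if (canal_contrast < 0 || canal_contrast > dentin_mean)
    stop("'canal_contrast' must lie in [0, dentin_mean]", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (c_arc_span <= 0 || c_arc_span > 2 * pi)
    stop("'c_arc_span' must be in (0, 2*pi]", call. = FALSE)
  structure(as.list(environment()), class = "phantom_params")
}

#' Render a dentin-pulp ROI phantom
#'
#' Builds the structure field (graded dentin minus the canal drop over the
#' canal mask), blurs it with a Gaussian of `blur_sigma`, adds white
#' Gaussian noise of `noise_sd`, clips to `[0, 2^bit_depth - 1]` and
#' quantizes. Same parameters and seed give bit-identical images.
#'
#' @param params a [phantom_params].
#' @param rng_seed integer seed for the noise draw.
#' @return List with `image` (a [grayscale_image], source tag
#'   `"synthetic"`) and `canal_mask` (logical matrix marking canal pixels
#'   before blur).
#' @export
make_tooth_phantom <- function(params, rng_seed = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  h <- params$roi_height; w <- params$roi_width
  rows <- matrix(seq_len(h), h, w)
  field <- params$dentin_mean +
    params$dentin_gradient * (rows - (h + 1) / 2)
  mask <- canal_mask(params)
  field <- field - params$canal_contrast * mask
  field <- gaussian_blur(field, params$blur_sigma)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  if (params$noise_sd > 0)
    field <- field + matrix(stats::rnorm(h * w, 0, params$noise_sd), h, w)
  maxval <- 2^params$bit_depth - 1
  img <- round(pmin(pmax(field, 0), maxval))
  list(image = grayscale_image(img, bit_depth = params$bit_depth,
                               source_resolution_tag = "synthetic"),
       canal_mask = mask)
}

# Logical mask of canal pixels (pre-blur), 0-based geometry on pixel centers.
canal_mask <- function(params) {
  h <- params$roi_height; w <- params$roi_width
  if (params$canal_contrast == 0 || params$canal_width <= 0)
    return(matrix(FALSE, h, w))
  r <- matrix(seq_len(h) - 1, h, w)        # row coordinate
  ccol <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  a <- 0.42 * h                             # vertical half-axis of the ellipse
  b <- params$canal_width / 2
  if (params$canal_shape == "simple") {
    ((r - cr) / a)^2 + ((ccol - cc) / b)^2 <= 1
  } else {
    # arc ribbon: same thickness, radius solved from the ellipse area budget
    # span * R0 * thickness = pi * a * b
    span <- params$c_arc_span
    t <- params$canal_width
    R0 <- pi * a * b / (span * t)
    d <- sqrt((r - cr)^2 + (ccol - cc)^2)
    ang <- atan2(r - cr, ccol - cc)         # 0 points right: the C opens right
    abs(d - R0) <= t / 2 & abs(ang) <= span / 2
  }
}
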