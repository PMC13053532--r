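#' Digital magnification by pixel interpolation
#'
#' Enlarges an image post-acquisition by resampling, the way on-screen zoom
#' does: no anatomical information is added, intermediate gray levels are
#' reconstructed from neighbours. Output shape is `round(factor * shape)`
#' per axis.
#'
#' Coordinate convention (pixel centers, "align corners = FALSE"): output
#' pixel `u` (0-based) samples the source at
#' \deqn{x = (u + 0.5) / f - 0.5}
#' where `f` is the per-axis ratio `out_size / in_size`. For `nearest` the
#' sample is `floor(x + 0.5)` clipped to the image; for `bilinear` the
#' coordinate is clamped to `[0, n - 1]` and the four neighbours are blended
#' linearly; `bicubic` uses the Catmull-Rom kernel (a = -0.5) with clamped
#' border indices. Results are rounded back to integers and clipped to
#' `[0, 2^bit_depth - 1]`.
#'
#' With an integer factor and `nearest`, every source pixel is duplicated
#' into an `f x f` block, so the value multiset per row is preserved and
#' pixel count scales by exactly `f^2`.
#'
#' @param img a [grayscale_image].
#' @param factor linear magnification factor, `>= 1` (downsampling is out of
#'   scope).
#' @param kernel `"nearest"`, `"bilinear"` or `"bicubic"`.
#' @return A [grayscale_image] with `zoom_state = "zoomed"` (unless
#'   `factor == 1`, which returns the input bit-identically), the factor and
#'   kernel recorded.
#' @export
digital_zoom <- function(img, factor, kernel = c("bilinear", "nearest", "bicubic")) {
  stopifnot(inherits(img, "grayscale_image"))
  kernel <- match.arg(kernel)
  if (factor < 1)
    stop("'factor' must be >= 1 (downsampling is out of scope)", call. = FALSE)
  if (factor == 1) return(img)
  m <- img$pixels
  nr <- nrow(m); nc <- ncol(m)
  out_r <- as.integer(round(factor * nr))
  out_c <- as.integer(round(factor * nc))
  fr <- out_r / nr; fc <- out_c / nc
  xr <- (seq_len(out_r) - 0.5) / fr - 0.5   # source row coordinate, 0-based
  xc <- (seq_len(out_c) - 0.5) / fc - 0.5
  out <- switch(kernel,
    nearest  = resample_nearest(m, xr, xc),
    bilinear = resample_bilinear(m, xr, xc),
    bicubic  = resample_bicubic(m, xr, xc))
  maxval <- 2^img$bit_depth - 1
  out <- round(pmin(pmax(out, 0), maxval))
  grayscale_image(out, bit_depth = img$bit_depth, zoom_state = "zoomed",
                  zoom_factor = factor, kernel = kernel,
                  source_resolution_tag = img$source_resolution_tag)
}

resample_nearest <- function(m, xr, xc) {
  ri <- pmin(pmax(floor(xr + 0.5), 0), nrow(m) - 1L) + 1L
  ci <- pmin(pmax(floor(xc + 0.5), 0), ncol(m) - 1L) + 1L
  m[ri, ci, drop = FALSE]
}

resample_bilinear <- function(m, xr, xc) {
  nr <- nrow(m); nc <- ncol(m)
  xr <- pmin(pmax(xr, 0), nr - 1)
  xc <- pmin(pmax(xc, 0), nc - 1)
  r0 <- pmin(floor(xr), nr - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(xc), nc - 2); c0 <- pmax(c0, 0)
  if (nr == 1L) r0 <- rep(0, length(xr))
  if (nc == 1L) c0 <- rep(0, length(xc))
  tr <- xr - r0; tc <- xc - c0
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  A <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  B <- m[r0 + 1L, c1 + 1L, drop = FALSE]
  C <- m[r1 + 1L, c0 + 1L, drop = FALSE]
  D <- m[r1 + 1L, c1 + 1L, drop = FALSE]
  wr <- matrix(tr, length(xr), length(xc))
  wc <- matrix(tc, length(xr), length(xc), byrow = TRUE)
  (1 - wr) * ((1 - wc) * A + wc * B) + wr * ((1 - wc) * C + wc * D)
}

# Catmull-Rom (Keys, a = -0.5) cubic weight
cubic_w <- function(t) {
  a <- -0.5
  at <- abs(t)
  ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

resample_bicubic <- function(m, xr, xc) {
  nr <- nrow(m); nc <- ncol(m)
  xr <- pmin(pmax(xr, 0), nr - 1)
  xc <- pmin(pmax(xc, 0), nc - 1)
  r0 <- floor(xr); c0 <- floor(xc)
  tr <- xr - r0; tc <- xc - c0
  out <- matrix(0, length(xr), length(xc))
  wsum <- matrix(0, length(xr), length(xc))
  for (dr in -1:2) {
    wr <- cubic_w(dr - tr)
    ri <- pmin(pmax(r0 + dr, 0), nr - 1) + 1L
    for (dc in -1:2) {
      wc <- cubic_w(dc - tc)
      ci <- pmin(pmax(c0 + dc, 0), nc - 1) + 1L
      w <- outer(wr, wc)
      out <- out + w * m[ri, ci, drop = FALSE]
      wsum <- wsum + w
    }
  }
  out / wsum
}
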