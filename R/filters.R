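# Reflect-padded 2D convolution shared by the Sobel operator and the
# phantom generator's Gaussian blur, so the whole package uses one border
# rule (reflection without edge repetition, i.e. pad index k maps to k+1).

reflect_pad <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc)
    stop("image too small for a padding of ", k, " pixels", call. = FALSE)
  ridx <- c((k + 1L):2L, 1L:nr, (nr - 1L):(nr - k))
  cidx <- c((k + 1L):2L, 1L:nc, (nc - 1L):(nc - k))
  m[ridx, cidx, drop = FALSE]
}

# Correlation with an odd-sized kernel; 'same' output, reflect border.
conv2_reflect <- function(m, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L, kr == kc)
  k <- (kr - 1L) %/% 2L
  p <- reflect_pad(m, k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (di in seq_len(kr)) {
    for (dj in seq_len(kc)) {
      w <- kern[di, dj]
      if (w != 0)
        out <- out + w * p[(di):(di + nr - 1L), (dj):(dj + nc - 1L)]
    }
  }
  out
}

#' Sobel gradient magnitude
#'
#' Applies the standard 3x3 Sobel kernels along rows and columns and returns
#' the per-pixel magnitude `sqrt(Gx^2 + Gy^2)`. Borders are handled by
#' reflect padding, which avoids spurious responses at ROI edges; output has
#' the same shape as the input. The magnitude is invariant under adding a
#' constant to the image.
#'
#' @param img a [grayscale_image] or a numeric matrix.
#' @return Numeric matrix of gradient magnitudes (same shape as the input).
#' @export
sobel_magnitude <- function(img) {
  m <- if (inherits(img, "grayscale_image")) img$pixels else img
  if (!is.matrix(m) || length(m) == 0L)
    stop("input image is empty", call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L) return(matrix(0, nrow(m), ncol(m)))
  # gx responds to horizontal (along-row) intensity change
  gx_k <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gy_k <- t(gx_k)
  gx <- conv2_reflect(m, gx_k)
  gy <- conv2_reflect(m, gy_k)
  sqrt(gx^2 + gy^2)
}

# Gaussian blur with a truncated (3 sigma) kernel, reflect border.
# sigma = 0 returns the input unchanged.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-((-k:k)^2) / (2 * sigma^2))
  g <- g / sum(g)
  conv2_reflect(m, outer(g, g))
}
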