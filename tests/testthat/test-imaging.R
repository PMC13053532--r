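test_that("PNG round trip preserves 8-bit grayscale values", {
  m <- matrix(200, 6, 7)
  p <- tempfile(fileext = ".png")
  write_image_png(grayscale_image(m), p, rescale = FALSE)
  img <- read_image(p, "PNG")
  expect_equal(img$pixels, m)
  expect_identical(img$zoom_state, "native")

  m2 <- rand_roi(9, 11, seed = 4)
  write_image_png(grayscale_image(m2), p, rescale = FALSE)
  expect_equal(read_image(p)$pixels, m2)
})

test_that("16-bit input is min-max rescaled to 8 bit with round-half-to-even", {
  p <- tempfile(fileext = ".tif")
  # endpoints map to endpoints
  m <- matrix(c(0, 65535, 65535, 0), 2, 2)
  tiff::writeTIFF(m / 65535, p, bits.per.sample = 16)
  expect_equal(sort(unique(as.vector(read_image(p, "TIFF")$pixels))), c(0, 255))
  # interior value at the rounding boundary: (300-100)/400*255 = 127.5 -> 128
  m <- matrix(c(100, 300, 500, 100, 300, 500), 2, 3)
  tiff::writeTIFF(m / 65535, p, bits.per.sample = 16)
  got <- read_image(p)$pixels
  expect_equal(sort(unique(as.vector(got))), c(0, 128, 255))
  # scalar hand computation for every pixel
  expect_equal(got, round(255 * (m - 100) / 400))
})

test_that("crop_roi copies the exact sub-block and preserves provenance", {
  m <- matrix(1:25, 5, 5)  # ramp image
  img <- grayscale_image(m, source_resolution_tag = "synthetic")
  # identity crop
  expect_equal(crop_roi(img, roi_rect(0, 0, 5, 5))$pixels, m)
  # 1x1 at origin
  expect_equal(as.vector(crop_roi(img, roi_rect(0, 0, 1, 1))$pixels), m[1, 1])
  # 3x2 crop checked index by index against a brute-force copy
  got <- crop_roi(img, roi_rect(1, 2, 3, 2))
  expected <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) expected[i, j] <- m[1 + i, 2 + j]
  expect_equal(got$pixels, expected)
  expect_identical(got$source_resolution_tag, "synthetic")
  # out of bounds
  expect_error(crop_roi(img, roi_rect(3, 3, 3, 3)), "bounds")
})

test_that("crop composition equals a single crop with composed offsets", {
  m <- rand_roi(12, 10, seed = 21)
  img <- grayscale_image(m)
  once <- crop_roi(img, roi_rect(2 + 3, 1 + 2, 4, 3))
  twice <- crop_roi(crop_roi(img, roi_rect(2, 1, 9, 8)), roi_rect(3, 2, 4, 3))
  expect_equal(twice$pixels, once$pixels)
})

test_that("pixel_count is height x width, also after zoom and re-selection", {
  img <- grayscale_image(matrix(7, 40, 50))
  expect_equal(pixel_count(img), 2000)
  expect_equal(pixel_count(digital_zoom(img, 2, "nearest")), 8000)
  # jittered zoomed ROI counts its own pixels, checked by enumeration
  sub <- crop_roi(digital_zoom(img, 2, "nearest"), roi_rect(3, 5, 37, 61))
  expect_equal(pixel_count(sub), sum(sub$pixels == 7))
})

test_that("invalid images and rectangles are rejected", {
  expect_error(grayscale_image(matrix(-1, 2, 2)), "within")
  expect_error(grayscale_image(matrix(256, 2, 2)), "within")
  expect_error(roi_rect(0, 0, 0, 3), ">= 1")
  expect_error(grayscale_image(matrix(1, 2, 2), zoom_factor = 0.5), ">= 1")
})
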