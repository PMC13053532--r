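test_that("factor 1 returns the image bit-identically", {
  img <- grayscale_image(rand_roi(9, 7, seed = 5))
  for (k in c("nearest", "bilinear", "bicubic"))
    expect_identical(digital_zoom(img, 1, k), img)
})

test_that("nearest integer zoom duplicates each pixel into an f x f block", {
  m <- rand_roi(6, 5, seed = 8)
  img <- grayscale_image(m)
  for (f in 2:3) {
    z <- digital_zoom(img, f, "nearest")
    expect_identical(z$zoom_state, "zoomed")
    expect_equal(z$zoom_factor, f)
    expect_equal(pixel_count(z), f^2 * pixel_count(img))
    expect_equal(z$pixels, m[rep(seq_len(nrow(m)), each = f),
                             rep(seq_len(ncol(m)), each = f)])
  }
})

test_that("bilinear zoom of a checkerboard matches the scalar formula", {
  m <- matrix(c(0, 255, 255, 0), 2, 2)
  z <- digital_zoom(grayscale_image(m), 2, "bilinear")
  expect_equal(dim(z$pixels), c(4, 4))
  # hand evaluation at every output pixel under the pixel-center mapping
  expected <- matrix(0, 4, 4)
  for (u in 0:3) for (v in 0:3)
    expected[u + 1, v + 1] <- round(scalar_bilinear(m, (u + 0.5) / 2 - 0.5,
                                                    (v + 0.5) / 2 - 0.5))
  expect_equal(z$pixels, expected)
  # a larger random case against the same scalar oracle
  m2 <- rand_roi(5, 6, seed = 31)
  z2 <- digital_zoom(grayscale_image(m2), 1.7, "bilinear")
  exp2 <- matrix(0, nrow(z2$pixels), ncol(z2$pixels))
  fr <- nrow(exp2) / 5; fc <- ncol(exp2) / 6
  for (u in seq_len(nrow(exp2)) - 1) for (v in seq_len(ncol(exp2)) - 1)
    exp2[u + 1, v + 1] <- round(scalar_bilinear(m2, (u + 0.5) / fr - 0.5,
                                                (v + 0.5) / fc - 0.5))
  expect_equal(z2$pixels, exp2)
})

test_that("zoom output stays within the 8-bit range for every kernel", {
  m <- matrix(c(rep(0, 18), rep(255, 18)), 6, 6)  # harsh edge for overshoot
  img <- grayscale_image(m)
  for (k in c("nearest", "bilinear", "bicubic")) {
    z <- digital_zoom(img, 1.6, k)
    expect_true(all(z$pixels >= 0 & z$pixels <= 255))
    expect_identical(z$kernel, k)
  }
})

test_that("bicubic zoom reproduces a linear ramp exactly in the interior", {
  # Catmull-Rom interpolates linear signals exactly where no clamping acts
  m <- matrix(rep(seq(40, 200, length.out = 9), each = 9), 9, 9, byrow = TRUE)
  z <- digital_zoom(grayscale_image(round(m)), 2, "bicubic")
  interior <- z$pixels[6:12, 6:12]
  # the ramp runs down rows: value at output row r is 40 + 20 * ((r-1.5)/2)
  expected <- outer(round(40 + 20 * (6:12 - 1.5) / 2), rep(1, 7))
  expect_true(max(abs(interior - expected)) <= 1)
})

test_that("downsampling factors are rejected", {
  img <- grayscale_image(matrix(1, 4, 4))
  expect_error(digital_zoom(img, 0.8), ">= 1")
})
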