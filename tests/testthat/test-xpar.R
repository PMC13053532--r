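test_that("depth map zero structure: Bij = Ai, Bij = 0 and Ai = 0 give zero", {
  # constant ROI: every pixel is its row maximum
  expect_equal(depth_map(matrix(77, 4, 5))$r_values, matrix(0, 4, 5))
  # a zero pixel in a positive row: sine factor kills it
  dm <- depth_map(matrix(c(255, 0, 10, 128), 2, 2, byrow = TRUE))
  expect_equal(dm$r_values[1, 2], 0)
  # an all-zero row is defined as zero
  m <- rbind(c(0, 0, 0), c(5, 9, 1))
  expect_equal(depth_map(m)$r_values[1, ], rep(0, 3))
  # conversely: zero iff one of the three conditions holds
  m2 <- rand_roi(12, 9, seed = 3)
  dm2 <- depth_map(m2)
  a <- apply(m2, 1, max)
  should_be_zero <- (m2 == a) | (m2 == 0) | (a == 0)
  expect_identical(dm2$r_values == 0, should_be_zero)
})

test_that("single-row depth value matches the scalar hand evaluation", {
  dm <- depth_map(grayscale_image(matrix(c(255, 128), 1, 2)))
  expect_equal(dm$row_max, 255)
  expect_equal(dm$r_values[1, 1], 0)
  expect_equal(dm$r_values[1, 2],
               (log(127^2 + 1) * sin(pi / 2 * 128 / 255))^2)
})

test_that("vectorized depth map equals the naive double loop exactly", {
  for (seed in 1:20) {
    m <- rand_roi(16, 16, seed = seed)
    expect_identical(depth_map(m)$r_values, loop_depth_map(m))
  }
  # include degenerate rows
  m <- rand_roi(8, 8, seed = 50); m[3, ] <- 0; m[5, ] <- 200
  expect_identical(depth_map(m)$r_values, loop_depth_map(m))
})

test_that("every Rij is bounded by [ln(Ai^2+1)]^2, strictly for 8-bit input", {
  for (seed in 21:25) {
    m <- rand_roi(16, 16, seed = seed)
    dm <- depth_map(m)
    bound <- (log(dm$row_max^2 + 1))^2
    expect_true(all(dm$r_values <= bound + 1e-12))
    positive <- dm$r_values > 0
    expect_true(all(dm$r_values[positive] <
                    (bound[row(dm$r_values)])[positive]))
  }
})

test_that("xpar_index is the mean of the map; zero iff all-zero", {
  expect_equal(xpar_index(depth_map(matrix(9, 3, 3))), 0)
  dm <- depth_map(matrix(c(255, 128, 64, 255), 2, 2, byrow = TRUE))
  expect_equal(xpar_index(dm), mean(loop_depth_map(matrix(c(255, 128, 64, 255),
                                                          2, 2, byrow = TRUE))))
  expect_gt(xpar_index(dm), 0)
})

test_that("power_xpar_index is the scaled power mean", {
  dm <- depth_map(matrix(9, 2, 2))   # all-zero map
  expect_equal(power_xpar_index(dm), 0)
  # direct summation oracle on a handmade map
  fake <- dm; fake$r_values <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(power_xpar_index(fake, p = 2, scale = 1), sqrt(7.5))
  expect_equal(power_xpar_index(fake, p = 1, scale = 10), 25)
  # constant map: scale * c for any p
  fake$r_values <- matrix(3.7, 2, 2)
  for (p in c(1, 2, 3.5)) expect_equal(power_xpar_index(fake, p = p), 37)
  expect_error(power_xpar_index(dm, p = 0.5), ">= 1")
})

test_that("power_xpar_index is monotone in every single Rij", {
  dm <- depth_map(rand_roi(6, 6, seed = 77))
  base <- power_xpar_index(dm)
  for (idx in sample(36, 5)) {
    bumped <- dm
    bumped$r_values[idx] <- bumped$r_values[idx] + 2
    expect_gt(power_xpar_index(bumped), base)
  }
})

test_that("indices are invariant under nearest integer zoom, pixel count x f^2", {
  set.seed(42)
  ph <- make_tooth_phantom(phantom_params(), rng_seed = 9)
  roi <- ph$image
  nz <- texture_metrics(roi, "non_zoomed")
  for (f in 2:3) {
    z <- texture_metrics(digital_zoom(roi, f, "nearest"), "zoomed")
    expect_equal(z$xpar, nz$xpar)
    expect_equal(z$power_xpar, nz$power_xpar)
    expect_equal(z$pixel_count, f^2 * nz$pixel_count)
  }
})

test_that("bilinear zoom on noisy phantoms shifts the indices (resampling bias)", {
  diffs <- sapply(1:8, function(s) {
    ph <- make_tooth_phantom(phantom_params(noise_sd = 2), rng_seed = s)
    b <- metrics_bundle(ph$image, zoom_factor = 1.5, kernel = "bilinear")
    c(xpar = b$zoomed$xpar - b$non_zoomed$xpar,
      pc = b$zoomed$pixel_count - b$non_zoomed$pixel_count)
  })
  expect_true(all(abs(diffs["xpar", ]) > 0))   # interpolation alters the index
  expect_true(all(diffs["pc", ] > 0))          # zoomed pixel count always higher
})

test_that("metrics_bundle with factor 1 differs only in the condition tag", {
  roi <- make_tooth_phantom(phantom_params(), rng_seed = 3)$image
  b <- metrics_bundle(roi, zoom_factor = 1)
  expect_identical(b$non_zoomed$condition, "non_zoomed")
  expect_identical(b$zoomed$condition, "zoomed")
  b$zoomed$condition <- "non_zoomed"
  expect_equal(b$zoomed, b$non_zoomed)
})

test_that("the log base only rescales the depth map", {
  m <- rand_roi(10, 10, seed = 12)
  r_e <- depth_map(m)$r_values
  r_10 <- depth_map(m, log_base = 10)$r_values
  expect_equal(r_10, r_e / log(10)^2)
})

test_that("depth maps export to CSV (exact) and PNG", {
  dm <- depth_map(rand_roi(6, 5, seed = 1))
  csv <- tempfile(fileext = ".csv"); pngf <- tempfile(fileext = ".png")
  export_depth_map(dm, csv)
  back <- as.matrix(utils::read.csv(csv, header = FALSE))
  dimnames(back) <- NULL
  expect_equal(back, dm$r_values)
  export_depth_map(dm, pngf)
  expect_true(file.exists(pngf))
})
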