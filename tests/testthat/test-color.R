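test_that("sRGB to CIELAB hits the white and black points and matches a reference", {
  w <- srgb_to_lab(c(255, 255, 255))
  expect_equal(unname(w[1, "L"]), 100, tolerance = 1e-6)
  expect_lt(abs(w[1, "a"]), 0.01)
  expect_lt(abs(w[1, "b"]), 0.01)
  expect_equal(unname(srgb_to_lab(c(0, 0, 0))[1, "L"]), 0, tolerance = 1e-8)

  set.seed(1)
  rgbs <- matrix(sample(0:255, 150, replace = TRUE), ncol = 3)
  ref <- farver::convert_colour(rgbs, from = "rgb", to = "lab")
  got <- srgb_to_lab(rgbs)
  expect_lt(max(abs(got - as.matrix(ref))), 0.01)

  expect_error(srgb_to_lab(c(-1, 0, 0)), "0..255")
  expect_error(srgb_to_lab(c(0, 0, 300)), "0..255")
})

test_that("CIEDE2000 is zero at identity, symmetric, and matches a reference implementation", {
  expect_equal(ciede2000(c(50, 10, -10), c(50, 10, -10)), 0)

  set.seed(2)
  lab1 <- cbind(runif(50, 0, 100), runif(50, -60, 60), runif(50, -60, 60))
  lab2 <- cbind(runif(50, 0, 100), runif(50, -60, 60), runif(50, -60, 60))
  expect_equal(ciede2000(lab1, lab2), ciede2000(lab2, lab1), tolerance = 1e-12)

  ref <- vapply(seq_len(50), function(i) {
    farver::compare_colour(lab1[i, , drop = FALSE], lab2[i, , drop = FALSE],
      from_space = "lab", method = "cie2000"
    )[1, 1]
  }, numeric(1))
  expect_equal(ciede2000(lab1, lab2), ref, tolerance = 1e-4)
})

test_that("downsampling keeps opaque area, drops background, and box-averages", {
  red <- array(0, c(400, 400, 4))
  red[, , 1] <- 1
  red[, , 4] <- 1
  ps <- downsample_and_mask(red, target = 20, object_id = 1)
  expect_equal(nrow(ps$lab), 400)
  expect_true(all(abs(sweep(ps$lab, 2, ps$lab[1, ])) < 1e-9))

  # left half transparent: about half the cells survive the alpha mask
  half <- red
  half[, 1:200, 4] <- 0
  ps2 <- downsample_and_mask(half, target = 20)
  expect_equal(nrow(ps2$lab), 200)

  # checkerboard blocks against the explicit block-mean oracle
  set.seed(3)
  img <- array(1, c(40, 40, 4))
  img[, , 1] <- matrix(runif(1600), 40, 40)
  img[, , 2] <- matrix(runif(1600), 40, 40)
  img[, , 3] <- matrix(runif(1600), 40, 40)
  ps3 <- downsample_and_mask(img, target = 20)
  oracle_rgb <- sapply(1:3, function(c) as.vector(block_mean_oracle(img[, , c], 20)))
  expect_equal(ps3$lab, srgb_to_lab(oracle_rgb * 255), tolerance = 1e-8)

  clear <- array(0, c(8, 8, 4))
  expect_error(downsample_and_mask(clear, target = 4), "empty pixel set")
  expect_error(downsample_and_mask(array(0, c(8, 8, 3))), "alpha")
})

test_that("PNG files round-trip through the downsampler", {
  img <- array(runif(20 * 20 * 4), c(20, 20, 4))
  img[, , 4] <- 1
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, path)
  ps <- downsample_and_mask(path, target = 10, object_id = 7)
  expect_s3_class(ps, "pixel_set")
  expect_equal(ps$object_id, 7)
  expect_equal(nrow(ps$lab), 100)
})

test_that("pair color score is the mean over the pixel cross product", {
  u1 <- srgb_to_lab(matrix(c(200, 30, 40), 5, 3, byrow = TRUE))
  u2 <- srgb_to_lab(matrix(c(200, 30, 40), 7, 3, byrow = TRUE))
  expect_equal(pair_color_score(u1, u2)$mean_delta_e, 0, tolerance = 1e-9)

  s1 <- srgb_to_lab(c(10, 200, 30))
  s2 <- srgb_to_lab(c(250, 60, 90))
  expect_equal(
    pair_color_score(s1, s2)$mean_delta_e,
    ciede2000(s1, s2)
  )

  # 3 x 2 pixel sets: brute-force 6-term mean
  set.seed(4)
  a <- cbind(runif(3, 0, 100), runif(3, -40, 40), runif(3, -40, 40))
  b <- cbind(runif(2, 0, 100), runif(2, -40, 40), runif(2, -40, 40))
  manual <- mean(c(
    ciede2000(a[1, ], b[1, ]), ciede2000(a[1, ], b[2, ]),
    ciede2000(a[2, ], b[1, ]), ciede2000(a[2, ], b[2, ]),
    ciede2000(a[3, ], b[1, ]), ciede2000(a[3, ], b[2, ])
  ))
  expect_equal(pair_color_score(a, b)$mean_delta_e, manual)

  # symmetric and invariant to pixel ordering
  expect_equal(
    pair_color_score(a, b)$mean_delta_e,
    pair_color_score(b, a)$mean_delta_e
  )
  expect_equal(
    pair_color_score(a[c(3, 1, 2), ], b)$mean_delta_e,
    pair_color_score(a, b)$mean_delta_e
  )
  # small common lightness shifts move the score only slightly
  shift <- cbind(rep(2, 3), 0, 0)
  base <- pair_color_score(a, b)$mean_delta_e
  shifted <- pair_color_score(a + shift, b + rbind(shift[1:2, ]))$mean_delta_e
  expect_equal(shifted, base, tolerance = 0.05)
})

test_that("color-shape correlation reports r, df and two-tailed p", {
  x <- c(1, 2, 3, 4, 5)
  res <- color_shape_correlation(x, 3 * x + 2)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$df, 3)

  n <- 435
  set.seed(5)
  res2 <- color_shape_correlation(runif(n), runif(n))
  expect_equal(res2$df, 433)

  expect_error(color_shape_correlation(rep(1, 10), runif(10)), "zero variance")
  expect_error(color_shape_correlation(1:2, 1:2), "length >= 3")
})

test_that("the correlation test holds its nominal size under the null", {
  set.seed(6)
  reps <- 500
  n <- 40
  rejections <- 0
  for (r in seq_len(reps)) {
    p <- color_shape_correlation(rnorm(n), rnorm(n))$p
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / reps, 0.02)
  expect_lte(rejections / reps, 0.08)
})
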