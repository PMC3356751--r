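test_that("otsu equals the exhaustive between-class-variance maximizer", {
  for (s in 1:30) {
    v <- withr::with_seed(s, {
      n <- sample(50:400, 1)
      # mixture of two modes with random spread, clipped to 0..255
      mu <- sort(sample(0:255, 2))
      pmin(255, pmax(0, round(c(rnorm(n, mu[1], 20), rnorm(n, mu[2], 20)))))
    })
    expect_identical(otsu_threshold(v), brute_force_otsu(v))
  }
})

test_that("otsu on a bimodal image puts the bright mode in foreground", {
  v <- withr::with_seed(1, pmin(255, pmax(0, round(
    c(rnorm(2000, 50, 10), rnorm(1000, 200, 10))))))
  img <- calibrated_image(matrix(v, 60, 50), 0.01)
  mask <- binarize(img, "otsu")
  bright <- img$pixels >= 150
  expect_true(all(mask$pixels[bright] == 1L))
  dark <- img$pixels <= 100
  expect_true(all(mask$pixels[dark] == 0L))
})

test_that("fixed thresholding is idempotent and errors when empty", {
  img <- calibrated_image(matrix(as.integer(c(0, 100, 200, 255)), 2, 2),
                          0.01)
  m1 <- binarize(img, "fixed", threshold = 128)
  img2 <- calibrated_image(m1$pixels * 255L, 0.01)
  m2 <- binarize(img2, "fixed", threshold = 128)
  expect_identical(m1$pixels, m2$pixels)
  zero <- calibrated_image(matrix(0L, 4, 4), 0.01)
  expect_error(binarize(zero, "fixed", threshold = 128), "empty foreground")
  expect_error(binarize(zero, "fixed", threshold = 128), "128")
})

test_that("polarity override inverts the foreground", {
  img <- calibrated_image(matrix(as.integer(c(0, 0, 0, 200)), 2, 2), 0.01)
  m <- binarize(img, "fixed", threshold = 128)
  mi <- binarize(img, "fixed", threshold = 128, invert = TRUE)
  expect_equal(sum(m$pixels), 1)
  expect_equal(sum(mi$pixels), 3)
})

test_that("labeling honors 8- vs 4-connectivity", {
  m <- matrix(0L, 5, 5); m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
})

test_that("extract_roi keeps the largest component and fills holes", {
  # disk plus 3 speckles
  m <- disk_mask(10, scale = 0.01)
  px <- m$pixels
  px[1, 1] <- 1L; px[2, ncol(px)] <- 1L; px[nrow(px), 3] <- 1L
  noisy <- grain_mask(px, 0.01, "noisy")
  roi <- extract_roi(noisy)
  expect_identical(roi$pixels, m$pixels)
  expect_equal(roi$provenance$components_dropped, 3L)
  # annulus -> filled disk
  n <- 31; ctr <- 16
  ann <- matrix(0L, n, n)
  for (i in 1:n) for (j in 1:n) {
    d <- sqrt((i - ctr)^2 + (j - ctr)^2)
    if (d <= 10 && d >= 6) ann[i, j] <- 1L
  }
  filled <- extract_roi(grain_mask(ann, 0.01, "annulus"))
  inner <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, `+`)) <= 10
  expect_true(all(filled$pixels[inner] == 1L))
  # and hole filling can be disabled
  kept <- extract_roi(grain_mask(ann, 0.01, "annulus"), fill_holes = FALSE)
  expect_identical(kept$pixels, ann)
})

test_that("equal-area tie breaks to the top-left component", {
  m <- matrix(0L, 10, 10)
  m[7:8, 7:8] <- 1L  # placed first in column-major order? no: rows 7-8
  m[2:3, 2:3] <- 1L  # top-left block, same area
  roi <- extract_roi(grain_mask(m, 0.01, "tie"), fill_holes = FALSE)
  expect_equal(sum(roi$pixels), 4)
  expect_equal(roi$pixels[2, 2], 1L)
  expect_equal(roi$pixels[7, 7], 0L)
  expect_equal(roi$provenance$tie_break, "topleft")
})

test_that("extract_roi always yields one 8-connected component", {
  for (s in 1:10) {
    px <- withr::with_seed(s, matrix(rbinom(900, 1, 0.3), 30, 30))
    if (sum(px) == 0L) next
    roi <- extract_roi(grain_mask(px, 0.01, "rand"))
    expect_equal(max(label_components(roi$pixels, 8)), 1)
  }
})
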