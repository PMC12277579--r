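test_that("bilinear downsampling halves dimensions and averages 2x2 blocks", {
  m <- matrix(c(10, 30, 20, 40), 2, 2)
  expect_equal(downsampleBilinear(m), matrix(25, 1, 1))

  u <- matrix(128, 6, 8)
  expect_equal(downsampleBilinear(u), matrix(128, 3, 4))

  # odd trailing row/column is dropped (floor semantics)
  odd <- matrix(runif(7 * 9, 0, 255), 7, 9)
  expect_equal(dim(downsampleBilinear(odd)), c(3L, 4L))

  # RGB arrays are averaged per channel
  arr <- array(0, c(4, 4, 3))
  arr[, , 1] <- 100; arr[, , 2] <- 50; arr[, , 3] <- 200
  d <- downsampleBilinear(arr)
  expect_equal(dim(d), c(2L, 2L, 3L))
  expect_true(all(d[, , 1] == 100) && all(d[, , 2] == 50))

  expect_error(downsampleBilinear(matrix(1, 1, 5)), "at least 2x2")
})

test_that("downsampling rounds half-up deterministically", {
  m <- matrix(c(0, 1, 0, 1), 2, 2)  # mean 0.5 -> 1
  expect_equal(downsampleBilinear(m), matrix(1, 1, 1))
})

test_that("gaussian smoothing preserves constants and reproduces its kernel on an impulse", {
  u <- array(77, c(10, 12, 3))
  expect_equal(gaussianSmooth(u, 5), u)

  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  out <- gaussianSmooth(imp, 5, sigma = 1.1)
  k1 <- exp(-(-2:2)^2 / (2 * 1.1^2)); k1 <- k1 / sum(k1)
  expect_equal(out[4:8, 4:8], outer(k1, k1), tolerance = 1e-12)
  expect_lt(out[6, 6], 1)
  expect_equal(sum(out), 1, tolerance = 1e-12)  # normalized kernel

  expect_error(gaussianSmooth(imp, 4), "odd")
})

test_that("HSV conversion matches the textbook definition", {
  px <- function(r, g, b) {
    a <- array(0, c(1, 1, 3)); a[1, 1, ] <- c(r, g, b); a
  }
  red <- rgbToHsv(px(255, 0, 0))
  expect_equal(as.vector(red), c(0, 255, 255))

  gray <- rgbToHsv(px(140, 140, 140))
  expect_equal(gray[1, 1, 2], 0)
  expect_equal(gray[1, 1, 3], 140)

  # independent evaluation of the standard formula for (128, 64, 32)
  mx <- 128; mn <- 32; delta <- mx - mn
  h_deg <- 60 * ((64 - 32) / delta)   # max is red
  expect_equal(as.vector(rgbToHsv(px(128, 64, 32))),
               c(h_deg / 360 * 255, delta / mx * 255, mx / 255 * 255),
               tolerance = 1e-10)

  expect_error(rgbToHsv(matrix(1, 4, 4)), "3-channel")
})

test_that("mean-shift smoothing has flat fixed points, keeps separated regions apart, and reduces noise variance", {
  u <- array(90, c(20, 20, 3))
  expect_equal(meanshiftSmooth(u, 5, 20), u)

  two <- array(0, c(20, 40, 3))
  two[, 1:20, ] <- 40; two[, 21:40, ] <- 200  # distance >> colorRadius
  out <- meanshiftSmooth(two, 5, 20)
  expect_equal(out, two)

  set.seed(42)
  noisy <- array(120 + rnorm(30 * 30 * 3, 0, 3), c(30, 30, 3))
  sm <- meanshiftSmooth(noisy, 5, 20)
  expect_lt(var(as.vector(sm)), var(as.vector(noisy)))

  expect_error(meanshiftSmooth(u, -1, 20), "positive")
})

test_that("Otsu threshold maximizes between-class variance (exhaustive-scan oracle)", {
  # clean bimodal image
  bi <- matrix(40, 50, 50); bi[20:35, 20:35] <- 220
  mk <- binarizeOtsu(bi, foreground = "bright")
  thr <- attr(mk, "threshold")
  # any threshold in [40, 220) separates the two levels; the scan picks
  # the lowest maximizer
  expect_gte(thr, 40); expect_lt(thr, 220)
  expect_equal(sum(mk), 16 * 16)

  # two equal Gaussian modes at 60 and 200 (exact mixture histogram,
  # rendered as pixel counts; the modes must overlap for the maximizer to
  # be unique -- with well-separated modes every split of the gap yields
  # the same between-class variance): the scan localizes the midpoint
  counts <- round(3e4 * (dnorm(0:255, 60, 30) + dnorm(0:255, 200, 30)))
  gm <- matrix(rep(0:255, counts), ncol = 1)
  t_or <- otsu_oracle(gm)
  expect_lt(abs(t_or - 130), 5)
  expect_lte(abs(attr(binarizeOtsu(gm), "threshold") - t_or), 1)

  # grain disk on white: foreground count matches the disk raster
  disk <- raster_disk(80, 80, 40, 40, 20)
  img <- matrix(240, 80, 80); img[disk == 1L] <- 70
  mk2 <- binarizeOtsu(img, foreground = "dark")
  expect_lt(abs(sum(mk2) - sum(disk)) / sum(disk), 0.02)

  expect_error(binarizeOtsu(matrix(7, 5, 5)), "constant")
})

test_that("otsu implementation agrees with the exhaustive scan across random images", {
  set.seed(11)
  for (i in 1:5) {
    img <- matrix(sample(0:255, 900, replace = TRUE,
                         prob = runif(256)^2), 30, 30)
    expect_lte(abs(attr(binarizeOtsu(img), "threshold") - otsu_oracle(img)),
               1)
  }
})

test_that("preprocessing pipeline separates grains from white background", {
  sc <- generateScene(5, touchFraction = 0, imageSize = c(700, 500),
                      seed = 21)
  mask <- preprocessPipeline(sceneImage(sc))
  lab <- grainsplit:::.label_components(mask)
  expect_equal(max(lab), 5L)
  expect_equal(dim(mask), c(250L, 350L))  # downsampled by 2

  sc2 <- generateScene(2, touchFraction = 1, imageSize = c(500, 400),
                       seed = 5)
  mask2 <- preprocessPipeline(sceneImage(sc2))
  expect_equal(max(grainsplit:::.label_components(mask2)), 1L)

  blank <- array(255, c(64, 64, 3))
  expect_error(preprocessPipeline(blank), "constant")
})
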