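test_that("contour extraction traces closed 8-connected boundaries", {
  m <- matrix(0L, 20, 20); m[6:15, 6:15] <- 1L
  cs <- extractContours(m, minArea = 1)
  expect_length(cs, 1)
  p <- contourPoints(cs[[1]])
  expect_equal(nrow(p), 36)  # boundary pixels of a 10x10 square
  # 8-connected and closed, including the wraparound step
  d <- pmax(abs(diff(p[, 1])), abs(diff(p[, 2])))
  expect_true(all(d == 1))
  expect_lte(max(abs(p[1, ] - p[36, ])), 1)

  expect_equal(extractContours(matrix(0L, 10, 10)), list())

  disks <- raster_disk(120, 200, 40, 40, 15) +
           raster_disk(120, 200, 40, 150, 18) +
           raster_disk(120, 200, 90, 100, 12)
  cs3 <- extractContours(disks, minArea = 1)
  expect_length(cs3, 3)
  areas <- sort(vapply(cs3, function(ct) ct@area, numeric(1)))
  expect_equal(areas, sort(c(sum(raster_disk(120, 200, 40, 40, 15)),
                             sum(raster_disk(120, 200, 40, 150, 18)),
                             sum(raster_disk(120, 200, 90, 100, 12)))))
})

test_that("minimum-area filter suppresses small components", {
  m <- raster_disk(60, 60, 30, 30, 12)
  m[5, 5] <- 1L; m[50, 8] <- 1L  # dust
  expect_length(extractContours(m, minArea = 30), 1)
  expect_length(extractContours(m, minArea = 1), 3)
})

test_that("CRF is ~0.5 on straight edges, lower at convex corners, higher in concave notches", {
  hp <- raster_halfplane(200, 200, 100)
  ct <- extractContours(hp, minArea = 1)[[1]]
  p <- contourPoints(ct)
  i <- which(p[, 1] == 100 & p[, 2] == 100)[1]
  v <- cornerResponse(ct, hp, i, radius = 7)
  expect_lt(abs(v - 0.5), 1 / 7)

  # 90-degree convex corner apex: one quarter of the disk is foreground
  sq <- matrix(0L, 100, 100); sq[30:70, 30:70] <- 1L
  ctq <- extractContours(sq, minArea = 1)[[1]]
  pq <- contourPoints(ctq)
  iq <- which(pq[, 1] == 30 & pq[, 2] == 30)[1]
  vq <- cornerResponse(ctq, sq, iq, radius = 7)
  expect_lt(abs(vq - 0.25), 0.08)

  # concave notch between touching disks exceeds the corner threshold
  dd <- raster_disk(120, 200, 60, 60, 30) | raster_disk(120, 200, 60, 119, 30)
  dd <- matrix(as.integer(dd), 120, 200)
  ctd <- extractContours(dd, minArea = 1)[[1]]
  prof <- crfValues(crfProfile(ctd, dd, radius = 7))
  expect_gt(max(prof), 0.6)
  expect_true(all(prof >= 0 & prof <= 1))
})

test_that("apex CRF increases monotonically with the wedge interior angle", {
  angles <- c(60, 90, 120, 180, 240, 270)
  vals <- vapply(angles, function(deg) {
    m <- raster_wedge(120, 120, 60, 40, deg)
    ct <- extractContours(m, minArea = 1)[[1]]
    p <- contourPoints(ct)
    i <- which(p[, 1] == 60 & p[, 2] == 40)[1]
    cornerResponse(ct, m, i, radius = 7)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("corner response matches the brute-force disk-enumeration oracle", {
  set.seed(13)
  masks <- list(
    raster_disk(70, 90, 35, 40, 22),
    matrix(as.integer(raster_disk(80, 140, 40, 45, 25) |
                      raster_disk(80, 140, 40, 94, 25)), 80, 140),
    raster_ellipse(90, 120, 45, 60, 40, 18, 0.6))
  for (m in masks) {
    ct <- extractContours(m, minArea = 1)[[1]]
    p <- contourPoints(ct)
    idx <- sample(nrow(p), 12)
    for (i in idx) {
      expect_identical(cornerResponse(ct, m, i, radius = 7),
                       crf_oracle(m, 1L, p[i, 1], p[i, 2], 7))
    }
  }
})

test_that("corner detection finds exactly the grain contact notches", {
  # convex shapes: no corners at threshold 0.6 for aspect ratios up to 3
  for (ar in c(1.2, 2, 3)) {
    m <- raster_ellipse(140, 200, 70, 100, 25 * ar, 25, 0.7)
    ct <- extractContours(m, minArea = 1)[[1]]
    expect_length(cornerIndices(detectCorners(ct, m, 7, 0.6)), 0)
  }

  # two touching disks: 2 corners within 3 px of the true notches
  dd <- matrix(as.integer(raster_disk(120, 200, 60, 60, 30) |
                          raster_disk(120, 200, 60, 119, 30)), 120, 200)
  ct <- extractContours(dd, minArea = 1)[[1]]
  co <- detectCorners(ct, dd, 7, 0.6)
  expect_length(cornerIndices(co), 2)
  pts <- contourPoints(ct)[cornerIndices(co), , drop = FALSE]
  # circle intersection points: col 89.5, rows 60 -+ 5.95
  d1 <- sqrt((pts[, 1] - 54.05)^2 + (pts[, 2] - 89.5)^2)
  d2 <- sqrt((pts[, 1] - 65.95)^2 + (pts[, 2] - 89.5)^2)
  expect_true(all(pmin(d1, d2) <= 3))

  # three disks in a row: 4 corners
  d3 <- matrix(0L, 140, 300)
  for (cx in c(60, 119, 178)) d3 <- d3 | raster_disk(140, 300, 70, cx, 30)
  d3 <- matrix(as.integer(d3), 140, 300)
  ct3 <- extractContours(d3, minArea = 1)[[1]]
  expect_length(cornerIndices(detectCorners(ct3, d3, 7, 0.6)), 4)
})

test_that("segments partition the contour points minus corner representatives", {
  dd <- matrix(as.integer(raster_disk(120, 200, 60, 60, 30) |
                          raster_disk(120, 200, 60, 119, 30)), 120, 200)
  ct <- extractContours(dd, minArea = 1)[[1]]
  co <- detectCorners(ct, dd, 7, 0.6)
  segs <- splitSegments(ct, co)
  n <- nrow(contourPoints(ct))
  expect_length(segs, 2)
  all_idx <- sort(c(unlist(segs), cornerIndices(co)))
  expect_equal(all_idx, seq_len(n))  # disjoint and jointly exhaustive

  # zero corners: one segment covering everything
  disk <- raster_disk(60, 60, 30, 30, 15)
  ctd <- extractContours(disk, minArea = 1)[[1]]
  segs0 <- splitSegments(ctd, detectCorners(ctd, disk, 7, 0.6))
  expect_length(segs0, 1)
  expect_equal(segs0[[1]], seq_len(nrow(contourPoints(ctd))))

  # synthetic 4-corner case: conservation of point counts
  d3 <- matrix(0L, 140, 300)
  for (cx in c(60, 119, 178)) d3 <- d3 | raster_disk(140, 300, 70, cx, 30)
  d3 <- matrix(as.integer(d3), 140, 300)
  ct3 <- extractContours(d3, minArea = 1)[[1]]
  co3 <- detectCorners(ct3, d3, 7, 0.6)
  segs3 <- splitSegments(ct3, co3)
  expect_length(segs3, 4)
  expect_equal(sum(lengths(segs3)), nrow(contourPoints(ct3)) - 4L)
})

test_that("cp estimator follows Ngrains = Ncorners/2 - Rclosed + 1", {
  expect_equal(estimateCountCp(0, 0), 1L)
  expect_equal(estimateCountCp(2, 0), 2L)
  expect_equal(estimateCountCp(4, 1), 2L)
  expect_equal(estimateCountCp(6, 0), 4L)
  expect_warning(v <- estimateCountCp(3, 0), "odd")
  expect_equal(v, 3L)
  expect_equal(estimateCountCp(0, 5), 1L)  # floored at one grain
})
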