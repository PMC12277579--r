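# shared constructions for partition tests
two_disk_mask <- function() {
  matrix(as.integer(raster_disk(120, 200, 60, 60, 30) |
                    raster_disk(120, 200, 60, 119, 30)), 120, 200)
}

segments_of <- function(mask, radius = 7, threshold = 0.6) {
  ct <- extractContours(mask, minArea = 1)[[1]]
  co <- detectCorners(ct, mask, radius, threshold)
  segs <- splitSegments(ct, co)
  segs <- segs[lengths(segs) > 0]
  pts <- cbind(x = contourPoints(ct)[, 2], y = contourPoints(ct)[, 1])
  list(contour = ct, corners = co,
       pixels = lapply(segs, function(ix) pts[ix, , drop = FALSE]))
}

in_region_fn <- function(mask) {
  function(ctr) {
    r <- round(ctr[2]); c <- round(ctr[1])
    r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) && mask[r, c] > 0
  }
}

test_that("set-partition enumeration is complete (Bell numbers)", {
  bell <- c(1, 2, 5, 15, 52, 203, 877)
  for (k in seq_along(bell)) expect_length(setPartitions(k), bell[k])
  # each assignment vector is a valid restricted-growth string
  for (p in setPartitions(4)) {
    expect_equal(p[1], 1L)
    expect_true(all(p <= cummax(c(1L, p[-length(p)] + 1L))))
  }
})

test_that("partition error prefers the true grouping of two touching grains", {
  dd <- two_disk_mask()
  s <- segments_of(dd)
  expect_length(s$pixels, 2)
  inR <- in_region_fn(dd)
  split2 <- partitionError(list(1L, 2L), s$pixels, inRegion = inR)
  merged <- partitionError(list(1:2), s$pixels, inRegion = inR)
  expect_lt(split2$total, merged$total)

  # a subset pooling arcs of two well-separated grains fits badly or not
  # at all: its error exceeds the correct two-subset split
  expect_true(!is.finite(merged$total) || merged$total > split2$total)
})

test_that("segments lying on one exact ellipse carry no dispersion penalty", {
  t1 <- seq(0.3, 2.5, length.out = 60); t2 <- seq(2.9, 5.6, length.out = 60)
  mk <- function(t) cbind(300 + 40 * cos(t), 200 + 22 * sin(t))
  segs <- list(mk(t1), mk(t2))
  pe <- partitionError(list(1:2), segs, lambda = 1)
  expect_lt(pe$total, 1e-6)  # residual ~0 and coincident centers
})

test_that("subsets that cannot form a real ellipse make the partition infeasible", {
  segs <- list(cbind(1:20, 0), cbind(1:20, 5))  # two parallel lines
  pe <- partitionError(list(1:2), segs)
  expect_identical(pe$total, Inf)
})

test_that("the best partition resolves touching grains and tolerates spurious corners", {
  # two touching disks -> 2 subsets
  dd <- two_disk_mask()
  s <- segments_of(dd)
  bp <- bestPartition(s$pixels, inRegion = in_region_fn(dd))
  expect_equal(grainCount(bp), 2L)

  # single segment (isolated grain): only one partition exists
  disk <- raster_disk(80, 80, 40, 40, 22)
  s1 <- segments_of(disk)
  bp1 <- bestPartition(s1$pixels, inRegion = in_region_fn(disk))
  expect_equal(grainCount(bp1), 1L)

  # chipped touching pair: the chip's extra segments get grouped with
  # their own grain, count stays 2
  m3 <- matrix(as.integer(raster_ellipse(160, 260, 80, 80, 50, 26, 0) |
                          raster_ellipse(160, 260, 80, 172, 48, 26, 0.2)),
               160, 260)
  bp_pt <- ellipse_point(80, 172, 48, 26, 0.2, 2.2)
  m3 <- raster_chip(m3, bp_pt["y"], bp_pt["x"], 7)
  s3 <- segments_of(m3)
  expect_gt(length(s3$pixels), 2)  # the chip created extra segment(s)
  bp3 <- bestPartition(s3$pixels, inRegion = in_region_fn(m3))
  expect_equal(grainCount(bp3), 2L)

  # too many segments is an explicit, catchable error
  expect_error(bestPartition(s3$pixels, maxSegments = 2L), "too complex")
})

test_that("best partition matches an independent brute-force evaluator", {
  masks <- list(
    two_disk_mask(),
    local({  # three disks in a row: 4 segments
      m <- matrix(0L, 140, 300)
      for (cx in c(60, 119, 178)) m <- m | raster_disk(140, 300, 70, cx, 30)
      matrix(as.integer(m), 140, 300)
    }),
    local({  # chipped pair: 4 segments
      m <- matrix(as.integer(
        raster_ellipse(160, 260, 80, 80, 50, 26, 0) |
        raster_ellipse(160, 260, 80, 172, 48, 26, 0.2)), 160, 260)
      p <- ellipse_point(80, 172, 48, 26, 0.2, 2.2)
      raster_chip(m, p["y"], p["x"], 7)
    }),
    local({  # chipped isolated grain
      m <- raster_ellipse(150, 200, 75, 100, 55, 25, 0.4)
      p <- ellipse_point(75, 100, 55, 25, 0.4, 4.1)
      raster_chip(m, p["y"], p["x"], 8)
    }))
  for (m in masks) {
    s <- segments_of(m)
    k <- length(s$pixels)
    expect_lte(k, 6)
    bp <- bestPartition(s$pixels, inRegion = in_region_fn(m))
    or <- oracle_best_partition(s$pixels, m > 0)
    expect_equal(canon_blocks(bp@subsets), canon_blocks(or$blocks))
    expect_equal(bp@totalError, or$err, tolerance = 1e-6)
  }
})

test_that("per-contour cpe counting is exact on constructed scenes", {
  # isolated ellipse: short-circuit to one grain with a faithful fit
  m <- raster_ellipse(150, 200, 75, 100, 55, 25, 0.4)
  ct <- extractContours(m, minArea = 1)[[1]]
  r <- countGrainsCpe(ct, m)
  expect_equal(r$count_cpe, 1L)
  f <- r$partition@fits[[1]]
  expect_lt(max(abs(f@center - c(100, 75))), 1)
  expect_lt(max(abs(f@semiAxes - c(55, 25))), 1)

  # chain of three touching disks
  d3 <- matrix(0L, 140, 300)
  for (cx in c(60, 119, 178)) d3 <- d3 | raster_disk(140, 300, 70, cx, 30)
  d3 <- matrix(as.integer(d3), 140, 300)
  r3 <- countGrainsCpe(extractContours(d3, minArea = 1)[[1]], d3)
  expect_equal(r3$count_cpe, 3L)
  # the middle disk's two opposite arcs must be grouped together
  sizes <- sort(lengths(r3$partition@subsets))
  expect_equal(sizes, c(1L, 1L, 2L))

  # chipped isolated grain: spurious corner does not split it
  p <- ellipse_point(75, 100, 55, 25, 0.4, 0.3)
  mc <- raster_chip(m, p["y"], p["x"], 6)
  rc <- countGrainsCpe(extractContours(mc, minArea = 1)[[1]], mc)
  expect_equal(rc$count_cpe, 1L)
})

test_that("every contour point ends up assigned to exactly one grain", {
  dd <- two_disk_mask()
  ct <- extractContours(dd, minArea = 1)[[1]]
  r <- countGrainsCpe(ct, dd)
  expect_length(r$assignment, nrow(contourPoints(ct)))
  expect_true(all(r$assignment %in% seq_len(r$count_cpe)))
})

test_that("grain counts are invariant to contour starting point and orientation", {
  dd <- two_disk_mask()
  ct <- extractContours(dd, minArea = 1)[[1]]
  p <- contourPoints(ct)
  n <- nrow(p)
  base <- countGrainsCpe(ct, dd)$count_cpe
  set.seed(5)
  for (shift in sample(n, 3)) {
    rot <- rbind(p[shift:n, , drop = FALSE], p[seq_len(shift - 1), , drop = FALSE])
    ct_r <- new("GrainContour", points = rot, label = ct@label, area = ct@area)
    expect_equal(countGrainsCpe(ct_r, dd)$count_cpe, base)
    ct_rev <- new("GrainContour", points = rot[n:1, , drop = FALSE],
                  label = ct@label, area = ct@area)
    expect_equal(countGrainsCpe(ct_rev, dd)$count_cpe, base)
  }
})
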