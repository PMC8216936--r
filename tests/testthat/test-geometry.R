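test_that("point-segment distance handles on-line and endpoint cases", {
  expect_equal(point_segment_distance(1, 0, 0, 0, 2, 0), 0)
  expect_equal(point_segment_distance(0, 5, 1, 0, 3, 0), sqrt(26))
  # perpendicular foot inside the segment
  expect_equal(point_segment_distance(1.5, 2, 0, 0, 3, 0), 2)
  # vertical (north-south) segments are fine
  expect_equal(point_segment_distance(2, 1, 0, 0, 0, 3), 2)
  expect_error(point_segment_distance(0, 0, 1, 1, 1, 1), "zero-length")
})

test_that("point-segment distance matches a dense-sampling oracle", {
  set.seed(41)
  u <- seq(0, 1, length.out = 2e4)
  for (i in 1:300) {
    p <- runif(2, -5, 5); a <- runif(2, -5, 5); b <- runif(2, -5, 5)
    if (all(a == b)) next
    d <- point_segment_distance(p[1], p[2], a[1], a[2], b[1], b[2])
    dense <- min(sqrt((p[1] - (a[1] + u * (b[1] - a[1])))^2 +
                        (p[2] - (a[2] + u * (b[2] - a[2])))^2))
    expect_lt(abs(d - dense), 1e-4)
  }
})

test_that("distance is endpoint-symmetric, endpoint-bounded and translation-invariant", {
  set.seed(42)
  for (i in 1:100) {
    p <- runif(2, -5, 5); a <- runif(2, -5, 5); b <- runif(2, -5, 5)
    tr <- runif(2, -100, 100)
    d1 <- point_segment_distance(p[1], p[2], a[1], a[2], b[1], b[2])
    d2 <- point_segment_distance(p[1], p[2], b[1], b[2], a[1], a[2])
    expect_equal(d1, d2)
    expect_lte(d1, sqrt(sum((p - a)^2)) + 1e-12)
    expect_lte(d1, sqrt(sum((p - b)^2)) + 1e-12)
    d3 <- point_segment_distance(p[1] + tr[1], p[2] + tr[2],
                                 a[1] + tr[1], a[2] + tr[2],
                                 b[1] + tr[1], b[2] + tr[2])
    expect_lt(abs(d1 - d3), 1e-9)
  }
})

test_that("minimum distance over transects matches a per-segment loop", {
  segs <- data.frame(x1 = c(0, 0), y1 = c(1, 2), x2 = c(5, 5), y2 = c(1, 2),
                     platform = 1)
  md <- min_distance_to_transects(2, 0, segs)
  expect_equal(md$distance, 1)
  expect_equal(md$segment, 1L)
  set.seed(43)
  for (i in 1:100) {
    L <- sample(1:6, 1)
    segs <- data.frame(x1 = runif(L, -5, 5), y1 = runif(L, -5, 5),
                       x2 = runif(L, -5, 5), y2 = runif(L, -5, 5))
    p <- runif(2, -5, 5)
    md <- min_distance_to_transects(p[1], p[2], segs)
    per <- vapply(seq_len(L), function(l)
      point_segment_distance(p[1], p[2], segs$x1[l], segs$y1[l],
                             segs$x2[l], segs$y2[l]), numeric(1))
    expect_equal(md$distance, min(per))
    expect_equal(md$segment, which.min(per))
  }
  expect_error(min_distance_to_transects(0, 0, segs[0, ]), "effort")
})

test_that("grid construction places centers and honors masks", {
  g <- ss_grid(2, 2, side = 1)
  expect_equal(g$G, 4L)
  expect_equal(g$centers,
               cbind(x = c(0.5, 1.5, 0.5, 1.5), y = c(0.5, 0.5, 1.5, 1.5)))
  gm <- ss_grid(2, 2, side = 1, mask = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(gm$G, 3L)
  expect_error(ss_grid(0, 2, 1), "positive")
  expect_error(ss_grid(2, 2, 1, mask = rep(FALSE, 4)), "empty")
})

test_that("pixel lookup is the inverse of the grid layout", {
  g <- ss_grid(10, 10, side = 0.7, origin = c(-2, 3))
  expect_equal(pixel_of_point(g$centers[, 1], g$centers[, 2], g),
               seq_len(g$G))
  # half-open convention: shared edge goes to the higher-index pixel
  expect_equal(pixel_of_point(-2 + 0.7, 3.1, g), 2L)
  # outer boundary is included
  expect_equal(pixel_of_point(-2 + 7, 3 + 7, g), 100L)
  set.seed(44)
  px <- runif(500, -2, 5); py <- runif(500, 3, 10)
  got <- pixel_of_point(px, py, g)
  for (i in seq_len(500)) {
    cx <- g$centers[got[i], 1]; cy <- g$centers[got[i], 2]
    expect_true(px[i] >= cx - 0.35 && px[i] < cx + 0.35 + 1e-9)
    expect_true(py[i] >= cy - 0.35 && py[i] < cy + 0.35 + 1e-9)
  }
  expect_error(pixel_of_point(99, 0, g), "outside")
  gm <- ss_grid(2, 2, side = 1, mask = c(TRUE, TRUE, FALSE, TRUE))
  expect_error(pixel_of_point(0.5, 1.5, gm), "masked")
})
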