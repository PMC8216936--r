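test_that("center-to-pixel distances are Euclidean between centers", {
  g <- ss_grid(4, 4, side = 1)
  d <- center_pixel_distances(1, g)
  expect_equal(d[1], 0)
  expect_equal(d[2], 1)   # adjacent pixel
  expect_equal(d[6], sqrt(2))
  set.seed(31)
  g2 <- ss_grid(5, 3, side = 0.8, origin = c(2, -1))
  for (s in sample(g2$G, 4)) {
    d <- center_pixel_distances(s, g2)
    oracle <- sqrt(rowSums(sweep(g2$centers, 2, g2$centers[s, ])^2))
    expect_equal(d, unname(oracle))
  }
})

test_that("space-use distribution normalizes across extreme movement scales", {
  set.seed(32)
  g <- ss_grid(10, 10, side = 1)
  X <- covariate_stack(array(rnorm(100 * 2), dim = c(100, 2, 1)))
  for (sg in 10^c(-2, -1, 0, 2, 6)) {
    p <- pi_movement(55, sg, c(0, 0), X, 1, g)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(is.finite(p)))
  }
  # sigma -> infinity with beta = 0: uniform
  p <- pi_movement(55, 1e6, c(0, 0), X, 1, g)
  expect_lt(max(abs(p - 1 / 100)), 1e-6)
  # equal distances get equal mass when beta = 0 (symmetry around center)
  p <- pi_movement(55, 1.3, c(0, 0), X, 1, g)
  expect_lt(abs(p[54] - p[56]), 1e-12)
  expect_lt(abs(p[45] - p[65]), 1e-12)
  # mass decreases with distance
  d <- center_pixel_distances(55, g)
  o <- order(d)
  expect_true(all(diff(p[o]) <= 1e-12))
})

test_that("three collinear pixels give the hand-computed softmax", {
  g <- ss_grid(3, 1, side = 1)
  X <- covariate_stack(array(0, dim = c(3, 1, 1)), standardize = FALSE)
  p <- pi_movement(1, 1, 0, X, 1, g)
  w <- c(1, exp(-0.5), exp(-2))
  expect_equal(p, w / sum(w), tolerance = 1e-12)
})

test_that("log movement matrix rows reproduce pi_movement", {
  set.seed(33)
  g <- ss_grid(6, 5, side = 1)
  X <- covariate_stack(array(rnorm(30 * 2), dim = c(30, 2, 1)))
  eta <- drop(matrix(X[, , 1], 30, 2) %*% c(0.5, -0.7))
  Ml <- lineSCR:::log_movement_matrix(lineSCR:::pixel_dist2_matrix(g),
                                      eta, 1.4)
  for (s in c(1, 13, 30))
    expect_equal(exp(Ml[s, ]),
                 pi_movement(s, 1.4, c(0.5, -0.7), X, 1, g),
                 tolerance = 1e-12)
})

test_that("location sampling is categorical over pixels, uniform within", {
  g <- ss_grid(4, 4, side = 1)
  pdeg <- rep(0, 16); pdeg[7] <- 1
  set.seed(34)
  loc <- sample_location(pdeg, g, n = 200)
  expect_true(all(loc$pixel == 7))
  expect_equal(pixel_of_point(loc$x, loc$y, g), loc$pixel)
  n <- 2e4
  loc <- sample_location(rep(1 / 16, 16), g, n = n)
  expect_equal(pixel_of_point(loc$x, loc$y, g), loc$pixel)
  # within-pixel offsets are uniform
  offx <- loc$x - g$centers[loc$pixel, 1]
  ks <- suppressWarnings(ks.test(offx, "punif", -0.5, 0.5))
  expect_gt(ks$p.value, 0.001)
})
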