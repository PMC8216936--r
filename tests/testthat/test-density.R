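test_that("covariate standardization yields mean 0, sd 1 per column", {
  set.seed(21)
  raw <- array(rnorm(50 * 2 * 3, mean = 5, sd = 3), dim = c(50, 2, 3))
  X <- covariate_stack(raw, names = c("a", "b"), square = "a")
  expect_equal(dimnames(X)[[2]], c("a", "b", "a2"))
  for (j in 1:3) {
    expect_lt(abs(mean(X[, j, ])), 1e-6)
    expect_lt(abs(sqrt(mean((X[, j, ] - mean(X[, j, ]))^2)) - 1), 1e-6)
  }
  expect_error(covariate_stack(array(1, dim = c(10, 1, 2))), "degenerate")
})

test_that("expected density is the exponentiated linear predictor", {
  set.seed(22)
  raw <- array(rnorm(30 * 2 * 2), dim = c(30, 2, 2))
  X <- covariate_stack(raw)
  expect_equal(expected_density(c(0, 0), X, 1), rep(1, 30))
  # single covariate, beta = 1, X = log c  ->  density c
  cvals <- seq(0.5, 3, length.out = 12)
  X1 <- array(log(cvals), dim = c(12, 1, 1))
  X1 <- covariate_stack(X1, standardize = FALSE)
  expect_equal(expected_density(1, X1, 1), cvals)
  beta <- c(0.7, -1.2)
  d <- expected_density(beta, X, 2)
  for (g in c(1, 7, 30))
    expect_equal(d[g], exp(sum(beta * X[g, , 2])))
})

test_that("activity-center distribution is a normalized, shift-invariant simplex", {
  set.seed(23)
  X <- covariate_stack(array(rnorm(40 * 2 * 1), dim = c(40, 2, 1)))
  p <- pi_density(c(1.3, -0.4), X, 1)
  expect_true(all(p >= 0))
  expect_lt(abs(sum(p) - 1), 1e-12)
  expect_equal(pi_density(c(0, 0), X, 1), rep(1 / 40, 40))
  # adding a pixel-constant to the log-predictor leaves pi unchanged:
  # append an all-ones column (unstandardized) with arbitrary coefficient
  Xc <- array(c(X, rep(1, 40)), dim = c(40, 3, 1))
  Xc <- covariate_stack(Xc, standardize = FALSE)
  expect_equal(pi_density(c(1.3, -0.4, 5.7), Xc, 1), p, tolerance = 1e-12)
  # G = 3 hand case: predictors (0, log 2, log 3)
  X3 <- covariate_stack(array(c(0, log(2), log(3)), dim = c(3, 1, 1)),
                        standardize = FALSE)
  expect_equal(pi_density(1, X3, 1), c(1, 2, 3) / 6)
})

test_that("activity-center sampling matches its distribution", {
  pdeg <- c(0, 0, 0, 0, 1, 0)
  expect_true(all(sample_activity_centers(pdeg, 50) == 5))
  set.seed(24)
  G <- 20; n <- 1e5
  s <- sample_activity_centers(rep(1 / G, G), n)
  freq <- tabulate(s, G) / n
  expect_lt(max(abs(freq - 1 / G)), 4 * sqrt(1 / (G * n)))
  set.seed(99); a <- sample_activity_centers(rep(1 / G, G), 100)
  set.seed(99); b <- sample_activity_centers(rep(1 / G, G), 100)
  expect_identical(a, b)
})

test_that("realized density counts centers of present individuals and conserves N", {
  g <- ss_grid(3, 3, side = 2)
  z <- rbind(c(1, 1), c(1, 0), c(0, 1))
  s <- rbind(c(1, 2), c(1, 5), c(9, 9))
  rd1 <- realized_density(z, s, g, 1)
  expect_equal(rd1[1], 2 / 4)
  expect_equal(sum(rd1) * 4, 2)
  expect_equal(realized_density(matrix(0, 3, 2), s, g, 1), rep(0, 9))
  set.seed(25)
  for (t in 1:2) {
    zz <- matrix(rbinom(40, 1, 0.5), 20, 2)
    ss <- matrix(sample(1:9, 40, TRUE), 20, 2)
    rd <- realized_density(zz, ss, g, t)
    loop <- numeric(9)
    for (i in 1:20) if (zz[i, t] == 1)
      loop[ss[i, t]] <- loop[ss[i, t]] + 1
    expect_equal(rd, loop / 4)
    expect_equal(sum(rd) * 4, sum(zz[, t]))
  }
})
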