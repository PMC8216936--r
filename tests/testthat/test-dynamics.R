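test_that("arrival and persistence link functions evaluate correctly", {
  expect_equal(gamma_t(c(0, 0, 0), 0.7), 0.5)
  expect_equal(gamma_t(c(0.5, 1.0, -0.5), 1), 0.731059, tolerance = 1e-6)
  expect_lt(gamma_t(c(-30, 0, 0), 0), 1e-12)
  expect_equal(phi_t(c(0, 0), 1.3), 0.5)
  expect_equal(phi_t(c(2, 0), 0), 0.880797, tolerance = 1e-6)
  tt <- seq(-2, 2, by = 0.5)
  expect_true(all(diff(phi_t(c(0.3, 0.8), tt)) > 0))
})

test_that("transition probability follows the persistence/arrival rule", {
  expect_equal(transition_prob(1, 0.9, 0.2), 0.9)
  expect_equal(transition_prob(0, 0.9, 0.2), 0.2)
  expect_equal(transition_prob(NULL, NA, 0.37), 0.37)
  expect_equal(transition_prob(c(1, 0, 1), 0.8, 0.1), c(0.8, 0.1, 0.8))
})

test_that("three-period presence marginal matches exhaustive path enumeration", {
  tt <- standardize_time(3)
  bg <- c(-0.4, 0.6, -0.2); bp <- c(0.8, 0.4)
  gam <- gamma_t(bg, tt); phi <- phi_t(bp, tt)
  # enumerate all 8 z-paths
  paths <- expand.grid(z1 = 0:1, z2 = 0:1, z3 = 0:1)
  pr <- apply(paths, 1, function(z) {
    p1 <- if (z[1] == 1) gam[1] else 1 - gam[1]
    q2 <- transition_prob(z[1], phi[1], gam[2])
    p2 <- if (z[2] == 1) q2 else 1 - q2
    q3 <- transition_prob(z[2], phi[2], gam[3])
    p3 <- if (z[3] == 1) q3 else 1 - q3
    p1 * p2 * p3
  })
  pz3 <- sum(pr[paths$z3 == 1])
  # against the forward recursion the simulator uses
  e <- gam[1]
  e <- phi[1] * e + gam[2] * (1 - e)
  e <- phi[2] * e + gam[3] * (1 - e)
  expect_equal(pz3, e, tolerance = 1e-12)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})

test_that("abundance, recruitment and superpopulation are exact counts", {
  z <- rbind(c(1, 1), c(0, 1), c(0, 0))
  expect_equal(derive_abundance(z), c(1L, 2L))
  expect_equal(derive_recruits(rbind(c(0, 1), c(0, 1), c(1, 1))),
               c(1L, 2L))
  expect_equal(superpopulation_size(rbind(c(1, 0), c(0, 1), c(0, 0))), 2L)
  expect_equal(derive_abundance(matrix(0, 4, 3)), c(0L, 0L, 0L))
  set.seed(7)
  z <- matrix(rbinom(60, 1, 0.4), 10, 6)
  N_loop <- integer(6); R_loop <- integer(6); super <- 0
  for (i in 1:10) if (any(z[i, ] == 1)) super <- super + 1
  for (t in 1:6) {
    N_loop[t] <- sum(z[, t])
    R_loop[t] <- if (t == 1) sum(z[, 1]) else
      sum(z[, t] == 1 & z[, t - 1] == 0)
  }
  expect_equal(derive_abundance(z), N_loop)
  expect_equal(derive_recruits(z), R_loop)
  expect_equal(superpopulation_size(z), super)
})

test_that("simulated populations follow the abundance recursion and allow re-entry", {
  tt <- standardize_time(4)
  bg <- c(-0.5, 0.3, -0.3); bp <- c(0.6, -0.2)
  gam <- gamma_t(bg, tt); phi <- phi_t(bp, tt)
  M <- 30; reps <- 1e4
  set.seed(11)
  # reps populations at once: rows are individuals across replicates
  z <- matrix(0L, M * reps, 4)
  z[, 1] <- rbinom(M * reps, 1, gam[1])
  for (t in 2:4)
    z[, t] <- rbinom(M * reps, 1, ifelse(z[, t - 1] == 1,
                                         phi[t - 1], gam[t]))
  EN <- numeric(4); EN[1] <- M * gam[1]
  for (t in 2:4) EN[t] <- phi[t - 1] * EN[t - 1] + gam[t] * (M - EN[t - 1])
  Nt <- sapply(1:4, function(t)
    colSums(matrix(z[, t], M, reps)))  # reps x 4
  for (t in 1:4) {
    se <- sd(Nt[, t]) / sqrt(reps)
    expect_lt(abs(mean(Nt[, t]) - EN[t]), 3 * se + 1e-9)
  }
  # re-entry happens: 1 -> 0 -> 1 patterns have positive frequency
  reentry <- z[, 1] == 1 & z[, 2] == 0 & z[, 3] == 1
  expect_gt(mean(reentry), 0)
})
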