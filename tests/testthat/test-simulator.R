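test_that("simulated covariates are standardized and seed-reproducible", {
  sc <- small_scenario()
  set.seed(71); X1 <- simulate_covariates(sc)
  set.seed(71); X2 <- simulate_covariates(sc)
  expect_identical(X1, X2)
  for (j in seq_len(dim(X1)[2])) {
    expect_lt(abs(mean(X1[, j, ])), 1e-6)
    expect_lt(abs(sqrt(mean((X1[, j, ] - mean(X1[, j, ]))^2)) - 1), 1e-6)
  }
  # a generator with no spatial, temporal or noise variation is degenerate
  flat <- small_scenario(cov_spatial_sd = 0, cov_trend_sd = 0,
                         cov_noise_sd = 0)
  set.seed(72)
  expect_error(simulate_covariates(flat), "degenerate")
})

test_that("population simulation respects degenerate dynamics", {
  # arrival probability ~ 0: nobody ever enters
  sc0 <- small_scenario(beta_gamma = c(-30, 0, 0))
  set.seed(73)
  X <- simulate_covariates(sc0)
  pop <- simulate_population(sc0, X)
  expect_equal(derive_abundance(pop$z), c(0L, 0L, 0L))
  # persistence ~ 1: no departures, abundance never decreases
  sc1 <- small_scenario(beta_phi = c(30, 0))
  pop <- simulate_population(sc1, X)
  expect_true(all(diff(derive_abundance(pop$z)) >= 0))
  expect_false(any(pop$z[, 1] == 1 & pop$z[, 2] == 0))
})

test_that("expected abundance of simulated populations follows the recursion", {
  sc <- small_scenario(M = 60)
  tt <- standardize_time(sc$T_periods)
  gam <- gamma_t(sc$beta_gamma[, 1], tt)
  phi <- phi_t(sc$beta_phi[, 1], tt)
  EN <- numeric(sc$T_periods); EN[1] <- sc$M * gam[1]
  for (t in 2:sc$T_periods)
    EN[t] <- phi[t - 1] * EN[t - 1] + gam[t] * (sc$M - EN[t - 1])
  set.seed(74)
  X <- simulate_covariates(sc)
  reps <- 2000
  Ns <- t(replicate(reps, derive_abundance(simulate_population(sc, X)$z)))
  for (t in seq_len(sc$T_periods)) {
    se <- sd(Ns[, t]) / sqrt(reps)
    expect_lt(abs(mean(Ns[, t]) - EN[t]), 3.5 * se + 1e-9)
  }
})

test_that("observation simulation respects detection extremes", {
  # p0 = 0: no detections
  sc0 <- small_scenario(det = det_params(list(form = "hn", p0 = 0,
                                              sigma = 0.5)))
  sim0 <- simulate_study(sc0, seed = 75)
  expect_equal(nrow(sim0$study$detections), 0L)
  expect_equal(sim0$study$n, 0L)
  # saturated detection: dense transects, p0 = 1, huge scale
  sc1 <- small_scenario(det = det_params(list(form = "hn", p0 = 1,
                                              sigma = 1e6)),
                        n_transects = 8)
  sim1 <- simulate_study(sc1, seed = 76)
  loc <- sim1$truth$locations
  expect_true(all(loc$detected == 1))
  # detections only of present individuals, with exact true locations
  sc <- small_scenario()
  sim <- simulate_study(sc, seed = 77)
  loc <- sim$truth$locations
  det <- loc[loc$detected == 1, ]
  for (r in seq_len(nrow(det)))
    expect_equal(sim$truth$z[det$individual[r], det$t[r]], 1L)
  # observed coordinates equal simulated true coordinates (no error model)
  obs <- sim$study$detections
  key_t <- paste(sim$truth$sim_id[obs$individual], obs$t, obs$k)
  key_l <- paste(det$individual, det$t, det$k)
  expect_setequal(key_t, key_l)
  m <- match(key_t, key_l)
  expect_equal(obs$x, det$x[m])
  expect_equal(obs$y, det$y[m])
})

test_that("empirical detection frequency tracks the detection curve", {
  # many individuals, one period/occasion: detection outcomes at given
  # mindist should match the half-normal curve within binomial error
  sc <- small_scenario(T_periods = 2, K = 1, M = 4000,
                       beta_gamma = c(30, 0, 0))
  sim <- simulate_study(sc, seed = 78)
  loc <- sim$truth$locations[sim$truth$locations$t == 1, ]
  bins <- cut(loc$mindist, breaks = seq(0, 1.2, by = 0.2))
  for (b in levels(bins)) {
    sel <- !is.na(bins) & bins == b
    if (sum(sel) < 200) next
    phat <- mean(loc$detected[sel])
    pbar <- mean(loc$p[sel])
    expect_lt(abs(phat - pbar),
              4 * sqrt(pbar * (1 - pbar) / sum(sel)) + 1e-9)
  }
  # detected fraction rises with p0 (monotonicity across a scenario ladder)
  frac <- sapply(c(0.2, 0.6, 1), function(p0) {
    scl <- small_scenario(det = det_params(list(form = "hn", p0 = p0,
                                                sigma = 0.6)))
    s <- simulate_study(scl, seed = 79)
    mean(s$truth$locations$detected)
  })
  expect_true(all(diff(frac) > 0))
})
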