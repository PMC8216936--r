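test_that("split-chain Gelman-Rubin flags divergence and passes iid chains", {
  set.seed(91)
  chains <- list(rnorm(1e4), rnorm(1e4))
  expect_lt(gelman_rubin(chains), 1.01)
  shifted <- list(rnorm(1e3), rnorm(1e3, mean = 10))
  expect_gt(gelman_rubin(shifted), 1.1)
  expect_error(gelman_rubin(list(rnorm(100))), "two chains")
  # a within-chain trend is caught by splitting
  trended <- list(seq(0, 1, length.out = 1000) + rnorm(1000, 0, 0.01),
                  seq(0, 1, length.out = 1000) + rnorm(1000, 0, 0.01))
  expect_gt(gelman_rubin(trended), 1.1)
  # matrix interface
  m1 <- cbind(a = rnorm(500), b = rnorm(500))
  m2 <- cbind(a = rnorm(500), b = rnorm(500, 5))
  rh <- gelman_rubin(list(m1, m2))
  expect_lt(rh["a"], 1.1); expect_gt(rh["b"], 1.1)
})

test_that("posterior summaries report moments, intervals and R-hat", {
  cons <- matrix(2.5, 100, 1, dimnames = list(NULL, "c"))
  s <- summarize_draws(list(cons, cons))
  expect_equal(s$mean, 2.5)
  expect_equal(s$q2.5, 2.5)
  expect_equal(s$q97.5, 2.5)
  expect_equal(s$rhat, 1)
  set.seed(92)
  z <- matrix(rnorm(4e4), ncol = 1, dimnames = list(NULL, "z"))
  s <- summarize_draws(z)
  expect_lt(abs(s$q2.5 + 1.96), 0.05)
  expect_lt(abs(s$q97.5 - 1.96), 0.05)
  # the table round-trips through CSV
  f <- tempfile(fileext = ".csv")
  write.csv(s, f, row.names = FALSE)
  s2 <- read.csv(f)
  expect_equal(s2$mean, s$mean)
  unlink(f)
})

test_that("with no data the sampler returns the uniform priors", {
  # arrival ~ 0 and fixed dynamics: nobody enters, nothing is detected,
  # so movement and detection parameters have flat likelihood and their
  # posterior must reproduce the Uniform priors
  sc <- small_scenario(beta_gamma = c(-30, 0, 0))
  sim <- simulate_study(sc, seed = 93)
  expect_equal(sim$study$n, 0L)
  fixed <- list(beta = sc$beta, bg = sc$beta_gamma, bp = sc$beta_phi)
  priors <- list(sigma_move = c(0.5, 3), det_sigma = c(0.2, 2),
                 p0 = c(0, 1))
  fit <- scr_fit(sim$study, M = 30, n_iter = 4000, n_burnin = 1000,
                 n_chains = 2, thin = 3, fixed = fixed, priors = priors,
                 seed = 94)
  d <- do.call(rbind, fit$draws)
  checks <- list("sigma_move.1" = priors$sigma_move, "p0.1.1" = priors$p0,
                 "det_sigma.1" = priors$det_sigma)
  for (par in names(checks)) {
    b <- checks[[par]]
    ks <- suppressWarnings(ks.test(d[, par], "punif", b[1], b[2]))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("fits are reproducible and acceptance rates are adapted", {
  sc <- small_scenario()
  sim <- simulate_study(sc, seed = 95)
  fit1 <- scr_fit(sim$study, M = 40, n_iter = 300, n_burnin = 150,
                  n_chains = 1, seed = 96)
  fit2 <- scr_fit(sim$study, M = 40, n_iter = 300, n_burnin = 150,
                  n_chains = 1, seed = 96)
  expect_identical(fit1$draws, fit2$draws)
  # post-burn-in acceptance rates should sit near the adaptation band
  acc <- fit1$accept[[1]]
  expect_true(all(acc[c("beta", "sigma_move.1", "p0.1.1")] > 0.05))
  expect_true(all(acc[c("beta", "sigma_move.1", "p0.1.1")] < 0.8))
})

test_that("posterior abundance respects the observed-count and M bounds", {
  sc <- small_scenario()
  sim <- simulate_study(sc, seed = 97)
  fit <- scr_fit(sim$study, M = 40, n_iter = 400, n_burnin = 200,
                 n_chains = 1, seed = 98)
  d <- fit$draws[[1]]
  obs_t <- sapply(seq_len(sc$T_periods), function(t)
    length(unique(sim$study$detections$individual[
      sim$study$detections$t == t])))
  for (t in seq_len(sc$T_periods)) {
    expect_true(all(d[, paste0("N.", t)] >= obs_t[t]))
    expect_true(all(d[, paste0("N.", t)] <= 40))
  }
  expect_true(all(d[, "Nsuper"] >= sim$study$n))
})

test_that("latent and marginalized likelihoods agree in posterior means", {
  # detection scale wider than a pixel, so the pixel-center quadrature of
  # the marginalized likelihood is accurate
  sc <- small_scenario(det = det_params(list(form = "hn", p0 = 0.6,
                                             sigma = 1.2)))
  sim <- simulate_study(sc, seed = 99)
  fits <- lapply(c("latent", "marginalized"), function(md)
    scr_fit(sim$study, M = 40, n_iter = 1500, n_burnin = 500,
            n_chains = 2, seed = 100, mode = md))
  s1 <- summary(fits[[1]]); s2 <- summary(fits[[2]])
  for (par in c("N.1", "N.2", "N.3", "Nsuper")) {
    m1 <- s1$mean[s1$parameter == par]
    m2 <- s2$mean[s2$parameter == par]
    expect_lt(abs(m1 - m2) / m1, 0.12)
  }
})
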