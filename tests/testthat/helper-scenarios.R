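# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite runs quickly.

# small scenario for fitting tests: 8 x 8 grid, sparse but workable data
small_scenario <- function(...) {
  args <- list(n_x = 8, n_y = 8, T_periods = 3, K = 2, M = 40,
               sigma_move = 1.5, n_transects = 4,
               det = det_params(list(form = "hn", p0 = 0.7, sigma = 0.6)))
  over <- list(...)
  args[names(over)] <- over
  do.call(scr_scenario, args)
}

# micro instance for the brute-force posterior oracle: G = 4 (2 x 2 grid),
# T = 2, K = 1, one transect, M = 4 with 2 observed individuals, all
# parameters fixed
micro_instance <- function() {
  grid <- ss_grid(2, 2, side = 1)
  segments <- data.frame(t = c(1, 2), k = 1, platform = 1,
                         x1 = 0, y1 = 1.0, x2 = 2, y2 = 1.0)
  detections <- data.frame(individual = c(1, 2), t = c(1, 2), k = 1,
                           x = c(0.6, 1.3), y = c(0.8, 1.4))
  X <- array(c(-1, 1, -1, 1, -1, -1, 1, 1), dim = c(4, 2, 1))
  X <- array(rep(X, 2), dim = c(4, 2, 2))
  X <- covariate_stack(X, names = c("c1", "c2"))
  study <- structure(list(
    grid = grid, T_periods = 2L, K = c(1L, 1L), segments = segments,
    detections = detections, n = 2L, groups = rep(NA_character_, 2),
    group_labels = "g1", V = 1L, X = X), class = "scr_study")
  pars <- list(beta = c(0.4, -0.3), sigma_move = 1.2,
               det = det_params(list(form = "hn", p0 = 0.6, sigma = 0.5)),
               bg = matrix(c(-0.5, 0.3, 0), 3, 1),
               bp = matrix(c(0.5, 0), 2, 1))
  list(study = study, pars = pars, M = 4L)
}

# exact per-individual posterior for the micro instance under the
# pixel-center-marginalized likelihood: enumerates (z1, z2, s1, s2) for an
# individual and returns marginals; detections is the individual's own
# rows of study$detections (possibly empty)
enumerate_micro_posterior <- function(mi, detections) {
  study <- mi$study; pars <- mi$pars
  grid <- study$grid
  tt <- standardize_time(2)
  gam <- gamma_t(pars$bg[, 1], tt)
  phi <- phi_t(pars$bp[, 1], tt)
  G <- grid$G
  piD <- sapply(1:2, function(t) pi_density(pars$beta, study$X, t))
  # per-period: movement matrix rows = s, cols = occupied pixel; pixel
  # center detection probabilities for the occasion
  pim <- lapply(1:2, function(t)
    t(sapply(1:G, function(g)
      pi_movement(g, pars$sigma_move, pars$beta, study$X, t, grid))))
  pdet <- lapply(1:2, function(t) {
    segs <- study$segments[study$segments$t == t, ]
    detection_prob(grid$centers[, 1], grid$centers[, 2], segs, pars$det)
  })
  # occasion likelihood given (z_t, s_t)
  occ_lik <- function(t, z, s) {
    det_rows <- detections[detections$t == t, , drop = FALSE]
    if (nrow(det_rows) == 0) {
      if (z == 0) return(1)
      return(sum(pim[[t]][s, ] * (1 - pdet[[t]])))
    }
    if (z == 0) return(0)
    segs <- study$segments[study$segments$t == t, ]
    u <- pixel_of_point(det_rows$x, det_rows$y, grid)
    p <- detection_prob(det_rows$x, det_rows$y, segs, pars$det)
    pim[[t]][s, u] * p  # within-pixel uniform density constant, dropped
  }
  post <- array(0, dim = c(2, 2, G, G))  # z1+1, z2+1, s1, s2
  for (z1 in 0:1) for (z2 in 0:1) for (s1 in 1:G) for (s2 in 1:G) {
    pz <- (if (z1 == 1) gam[1] else 1 - gam[1]) *
      (if (z1 == 1) (if (z2 == 1) phi[1] else 1 - phi[1])
       else (if (z2 == 1) gam[2] else 1 - gam[2]))
    post[z1 + 1, z2 + 1, s1, s2] <- pz * piD[s1, 1] * piD[s2, 2] *
      occ_lik(1, z1, s1) * occ_lik(2, z2, s2)
  }
  post <- post / sum(post)
  list(pz1 = sum(post[2, , , ]), pz2 = sum(post[, 2, , ]),
       ps1 = apply(post, 3, sum), ps2 = apply(post, 4, sum))
}
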