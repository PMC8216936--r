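#' Simulation scenario
#'
#' Bundle of everything needed to forward-simulate a complete line-transect
#' capture-recapture study from the full hierarchical model: grid, survey
#' design, covariate generator, and true parameter values. The defaults are
#' the package's "desk" scenario — a 15 x 15 unit grid (G = 225 pixels of
#' side 1), T = 5 primary periods of K = 3 occasions, M = 150 augmented
#' individuals, a single demographic group and platform, two smooth habitat
#' covariates with squared companions, and 6 parallel east-west transects
#' per occasion with occasion-varying offsets — sized so that full
#' parameter-recovery runs complete in minutes.
#'
#' True parameter defaults give a seasonal occupancy pulse (arrival rising
#' then falling over the season, persistence declining) with per-period
#' abundance of roughly 20-80 individuals, movement scale of 2 pixel widths,
#' and a half-normal detection function with baseline 0.7 and scale half a
#' pixel width.
#'
#' @param n_x,n_y,side,origin,mask grid definition, see [ss_grid()].
#' @param T_periods number of primary periods.
#' @param K occasions per primary period (scalar or length-T vector).
#' @param M augmented population size.
#' @param J number of base habitat covariates.
#' @param square logical: append squared companions to every base covariate.
#' @param beta habitat coefficients (length J, or J' = 2J when
#'   \code{square}).
#' @param sigma_move movement scale per group (length V).
#' @param det detection parameters, a [det_params()] object (one entry per
#'   platform; \code{p0} vectors of length V).
#' @param beta_gamma 3 x V matrix (or length-3 vector) of arrival
#'   coefficients.
#' @param beta_phi 2 x V matrix (or length-2 vector) of persistence
#'   coefficients.
#' @param pi_group true group-membership probabilities (length V).
#' @param p_group_known probability that a detected individual's group
#'   label is recorded.
#' @param n_transects parallel transects per occasion.
#' @param platforms_cycle platform indices assigned to successive transect
#'   lines, recycled.
#' @param cov_spatial_sd,cov_trend_sd,cov_noise_sd covariate generator:
#'   sd of the random low-order polynomial coefficients of the spatial
#'   surface, of the per-period temporal shift, and of i.i.d. pixel noise.
#' @return A list of class \code{"scr_scenario"}.
#' @export
scr_scenario <- function(n_x = 15, n_y = 15, side = 1, origin = c(0, 0),
                         mask = NULL,
                         T_periods = 5, K = 3, M = 150,
                         J = 2, square = TRUE,
                         beta = c(0.4, 0.3, -0.3, -0.2),
                         sigma_move = 2,
                         det = det_params(
                           list(form = "hn", p0 = 0.7, sigma = 0.5)),
                         beta_gamma = c(-0.8, 0.3, -0.3),
                         beta_phi = c(1.2, -0.3),
                         pi_group = 1,
                         p_group_known = 1,
                         n_transects = 6,
                         platforms_cycle = 1,
                         cov_spatial_sd = 1, cov_trend_sd = 0.5,
                         cov_noise_sd = 0.3) {
  V <- length(pi_group)
  beta_gamma <- matrix(beta_gamma, nrow = 3)
  beta_phi <- matrix(beta_phi, nrow = 2)
  stopifnot(ncol(beta_gamma) == V, ncol(beta_phi) == V,
            length(sigma_move) == V, all(sigma_move > 0),
            abs(sum(pi_group) - 1) < 1e-8, M >= 1, T_periods >= 2)
  K <- rep_len(as.integer(K), T_periods)
  Jp <- if (square) 2L * J else as.integer(J)
  stopifnot(length(beta) == Jp)
  for (p in det) stopifnot(length(p$p0) %in% c(1, V))
  structure(list(
    n_x = n_x, n_y = n_y, side = side, origin = origin, mask = mask,
    T_periods = as.integer(T_periods), K = K, M = as.integer(M),
    J = as.integer(J), square = square, beta = beta,
    sigma_move = sigma_move, det = det,
    beta_gamma = beta_gamma, beta_phi = beta_phi,
    pi_group = pi_group, V = V, p_group_known = p_group_known,
    n_transects = as.integer(n_transects),
    platforms_cycle = as.integer(platforms_cycle),
    cov_spatial_sd = cov_spatial_sd, cov_trend_sd = cov_trend_sd,
    cov_noise_sd = cov_noise_sd
  ), class = "scr_scenario")
}

#' Simulate smooth habitat-covariate surfaces
#'
#' Generates J synthetic covariate surfaces over the grid and periods: each
#' is a random low-order (quadratic) spatial polynomial plus a per-period
#' temporal shift plus i.i.d. pixel noise, standardized and (optionally)
#' given squared companion columns via [covariate_stack()]. These stand in
#' for remotely sensed fields such as sea-surface temperature or wind
#' speed: smooth in space, drifting over the season, with fine-scale noise.
#'
#' @param scenario an [scr_scenario()].
#' @param grid the grid to simulate on (defaults to the scenario's).
#' @return A \code{"scr_covariates"} array (see [covariate_stack()]).
#' @export
simulate_covariates <- function(scenario, grid = scenario_grid(scenario)) {
  Tt <- scenario$T_periods
  G <- grid$G
  xs <- scale01(grid$centers[, 1]); ys <- scale01(grid$centers[, 2])
  basis <- cbind(xs, ys, xs * ys, xs^2, ys^2)
  raw <- array(NA_real_, dim = c(G, scenario$J, Tt))
  w <- if (Tt > 1) standardize_time(Tt) else 0
  for (j in seq_len(scenario$J)) {
    coef <- stats::rnorm(ncol(basis), 0, scenario$cov_spatial_sd)
    spat <- drop(basis %*% coef)
    tau <- stats::rnorm(1, 0, scenario$cov_trend_sd)
    for (t in seq_len(Tt))
      raw[, j, t] <- spat + tau * w[t] +
        stats::rnorm(G, 0, scenario$cov_noise_sd)
  }
  covariate_stack(raw, names = paste0("cov", seq_len(scenario$J)),
                  square = if (scenario$square) seq_len(scenario$J))
}

scale01 <- function(v) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(0, length(v)))
  2 * (v - r[1]) / (r[2] - r[1]) - 1
}

#' @rdname simulate_covariates
#' @export
scenario_grid <- function(scenario) {
  ss_grid(scenario$n_x, scenario$n_y, scenario$side, scenario$origin,
          scenario$mask)
}

#' Simulate the survey design
#'
#' Lays out \code{n_transects} parallel east-west transect lines spanning
#' the grid on every occasion, with a uniformly random north-south offset
#' per occasion (so coverage varies between occasions, as in real aerial
#' programs where planned lines shift between flights). Platforms are
#' assigned to successive lines by recycling \code{platforms_cycle}.
#'
#' @param scenario an [scr_scenario()].
#' @return Data frame of segments with columns
#'   \code{t, k, platform, x1, y1, x2, y2}.
#' @export
simulate_transects <- function(scenario) {
  g <- scenario_grid(scenario)
  x_lo <- g$origin[1]; x_hi <- g$origin[1] + g$n_x * g$side
  height <- g$n_y * g$side
  spacing <- height / scenario$n_transects
  out <- list()
  for (t in seq_len(scenario$T_periods)) {
    for (k in seq_len(scenario$K[t])) {
      off <- stats::runif(1, 0.05, 0.95) * spacing
      ys <- g$origin[2] + off + (seq_len(scenario$n_transects) - 1) * spacing
      out[[length(out) + 1L]] <- data.frame(
        t = t, k = k,
        platform = rep_len(scenario$platforms_cycle,
                           scenario$n_transects),
        x1 = x_lo, y1 = ys, x2 = x_hi, y2 = ys)
    }
  }
  do.call(rbind, out)
}

#' Simulate the latent population
#'
#' Forward-simulates group membership, the presence-state chain z, and
#' per-period activity centers s for all M augmented individuals.
#'
#' @param scenario an [scr_scenario()].
#' @param X covariate stack (from [simulate_covariates()]).
#' @param grid the state-space grid.
#' @return A list with \code{z} (M x T), \code{group} (length M),
#'   \code{s} (M x T).
#' @export
simulate_population <- function(scenario, X, grid = scenario_grid(scenario)) {
  M <- scenario$M; Tt <- scenario$T_periods
  tt <- standardize_time(Tt)
  group <- sample.int(scenario$V, M, replace = TRUE,
                      prob = scenario$pi_group)
  Gam <- sapply(seq_len(scenario$V),
                function(v) gamma_t(scenario$beta_gamma[, v], tt))
  Phi <- sapply(seq_len(scenario$V),
                function(v) phi_t(scenario$beta_phi[, v], tt))
  Gam <- matrix(Gam, nrow = Tt); Phi <- matrix(Phi, nrow = Tt)
  z <- matrix(0L, M, Tt)
  z[, 1] <- stats::rbinom(M, 1, Gam[1, group])
  for (t in 2:Tt) {
    pr <- transition_prob(z[, t - 1], Phi[t - 1, group], Gam[t, group])
    z[, t] <- stats::rbinom(M, 1, pr)
  }
  s <- matrix(0L, M, Tt)
  for (t in seq_len(Tt))
    s[, t] <- sample_activity_centers(pi_density(scenario$beta, X, t), M)
  list(z = z, group = group, s = s)
}

#' Simulate the observation process
#'
#' For every secondary occasion, each individual present in that primary
#' period occupies a pixel drawn from its space-use distribution and an
#' exact location uniform within the pixel; it is then detected with the
#' probability given by the detection function of the platform that flew
#' the nearest transect segment. Individuals absent from the population are
#' never detected.
#'
#' @param scenario an [scr_scenario()].
#' @param pop population state from [simulate_population()].
#' @param segments survey design from [simulate_transects()].
#' @param X covariate stack.
#' @param grid the state-space grid.
#' @return A list with \code{detections} (data frame: individual, t, k,
#'   x, y) and \code{locations} (data frame of all true occasion locations
#'   of present individuals, with mindist, platform, detection probability
#'   and outcome) — the latter is the truth table used by tests.
#' @export
simulate_survey <- function(scenario, pop, segments, X,
                            grid = scenario_grid(scenario)) {
  Tt <- scenario$T_periods
  D2 <- pixel_dist2_matrix(grid)
  loc <- list()
  for (t in seq_len(Tt)) {
    eta <- density_linpred(scenario$beta, X, t)
    Mlog <- lapply(scenario$sigma_move,
                   function(sg) log_movement_matrix(D2, eta, sg))
    for (k in seq_len(scenario$K[t])) {
      segs <- segments[segments$t == t & segments$k == k, , drop = FALSE]
      pres <- which(pop$z[, t] == 1)
      if (!length(pres)) next
      gpix <- integer(length(pres))
      for (v in seq_len(scenario$V)) {
        sel <- pop$group[pres] == v
        if (!any(sel)) next
        lw <- Mlog[[v]][pop$s[pres[sel], t], , drop = FALSE]
        gpix[sel] <- gumbel_argmax(lw)
      }
      half <- grid$side / 2
      ux <- grid$centers[gpix, 1] + stats::runif(length(pres), -half, half)
      uy <- grid$centers[gpix, 2] + stats::runif(length(pres), -half, half)
      if (nrow(segs)) {
        md <- min_distance_to_transects(ux, uy, segs)
        plat <- segs$platform[md$segment]
        p <- numeric(length(pres))
        for (v in seq_len(scenario$V)) {
          sel <- pop$group[pres] == v
          if (!any(sel)) next
          p[sel] <- p_from_dist(md$distance[sel], plat[sel],
                                scenario$det, v)
        }
        dist <- md$distance
      } else {
        p <- rep(0, length(pres)); plat <- rep(NA_integer_, length(pres))
        dist <- rep(NA_real_, length(pres))
      }
      y <- stats::rbinom(length(pres), 1, p)
      loc[[length(loc) + 1L]] <- data.frame(
        individual = pres, t = t, k = k, pixel = gpix, x = ux, y_coord = uy,
        mindist = dist, platform = plat, p = p, detected = y)
    }
  }
  loc <- if (length(loc)) do.call(rbind, loc) else
    data.frame(individual = integer(), t = integer(), k = integer(),
               pixel = integer(), x = numeric(), y_coord = numeric(),
               mindist = numeric(), platform = integer(), p = numeric(),
               detected = integer())
  det <- loc[loc$detected == 1,
             c("individual", "t", "k", "x", "y_coord")]
  names(det) <- c("individual", "t", "k", "x", "y")
  rownames(det) <- NULL
  list(detections = det, locations = loc)
}

# detection probability from precomputed mindist + platform index
p_from_dist <- function(dist, platform, det, group) {
  p <- numeric(length(dist))
  for (pl in unique(platform)) {
    sel <- platform == pl
    pp <- det[[pl]]
    p0 <- if (length(pp$p0) == 1) pp$p0 else pp$p0[group]
    p[sel] <- switch(pp$form,
      hn = p_halfnormal(dist[sel], p0, pp$sigma),
      hr = p_hazardrate(dist[sel], p0, pp$sigma, pp$b))
  }
  p
}

# vectorized categorical draws from rows of a log-weight matrix
gumbel_argmax <- function(lw) {
  gum <- -log(-log(stats::runif(length(lw))))
  max.col(lw + matrix(gum, nrow(lw), ncol(lw)), ties.method = "first")
}

#' Simulate a complete study
#'
#' Runs the full generative model — covariates, survey design, population,
#' observation — and packages the observed portion as an \code{scr_study}
#' (what a field program would deliver) alongside the complete truth (true
#' parameters and latent states) for testing and parameter-recovery work.
#'
#' Observed individuals are renumbered 1..n in order of first detection;
#' group labels of detected individuals are recorded with probability
#' \code{p_group_known} and otherwise left unknown.
#'
#' @param scenario an [scr_scenario()].
#' @param seed optional integer seed.
#' @return A list with elements \code{study} (class \code{"scr_study"})
#'   and \code{truth}.
#' @export
simulate_study <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- scenario_grid(scenario)
  X <- simulate_covariates(scenario, grid)
  segments <- simulate_transects(scenario)
  pop <- simulate_population(scenario, X, grid)
  obs <- simulate_survey(scenario, pop, segments, X, grid)
  det <- obs$detections
  first <- unique(det$individual)
  obs_id <- match(det$individual, first)
  n <- length(first)
  grp_lab <- rep(NA_character_, n)
  if (n) {
    known <- stats::runif(n) < scenario$p_group_known
    grp_lab[known] <- paste0("g", pop$group[first[known]])
  }
  detections <- data.frame(individual = obs_id, t = det$t, k = det$k,
                           x = det$x, y = det$y)
  study <- structure(list(
    grid = grid, T_periods = scenario$T_periods, K = scenario$K,
    segments = segments, detections = detections,
    n = n, groups = grp_lab,
    group_labels = paste0("g", seq_len(scenario$V)), V = scenario$V,
    X = X
  ), class = "scr_study")
  truth <- list(scenario = scenario, z = pop$z, s = pop$s,
                group = pop$group, locations = obs$locations,
                sim_id = first,
                N = derive_abundance(pop$z), R = derive_recruits(pop$z),
                Nsuper = superpopulation_size(pop$z))
  list(study = study, truth = truth)
}

#' @export
print.scr_study <- function(x, ...) {
  cat(sprintf(
    "Line-transect SCR study: %d individuals, %d detections, T = %d, G = %d\n",
    x$n, nrow(x$detections), x$T_periods, x$grid$G))
  invisible(x)
}
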