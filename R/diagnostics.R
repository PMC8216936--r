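#' Gelman-Rubin convergence diagnostic (split chains)
#'
#' Potential scale reduction factor computed on split chains: each chain's
#' kept draws are halved, so within-chain trends inflate the statistic and
#' a single wandering chain cannot hide. Values near 1 indicate the chains
#' are sampling the same distribution; values above 1.1 are conventionally
#' taken as non-convergence.
#'
#' @param chains a list of numeric vectors (one per chain, equal lengths),
#'   or a list of equal-dimension matrices (columns = parameters), with at
#'   least two chains.
#' @return A single R-hat value for vector input; a named vector (one per
#'   column) for matrix input. Constant chains return 1.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("need a list of at least two chains")
  if (is.matrix(chains[[1]])) {
    p <- ncol(chains[[1]])
    out <- vapply(seq_len(p), function(j)
      gelman_rubin(lapply(chains, function(m) m[, j])), numeric(1))
    names(out) <- colnames(chains[[1]])
    return(out)
  }
  n <- unique(vapply(chains, length, integer(1)))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 4) stop("chains too short to split")
  half <- floor(n / 2)
  splits <- unlist(lapply(chains, function(x)
    list(x[seq_len(half)], x[seq_len(half) + (n - half)])),
    recursive = FALSE)
  m <- length(splits)
  means <- vapply(splits, mean, numeric(1))
  vars <- vapply(splits, stats::var, numeric(1))
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Posterior summary table
#'
#' Mean, sd, 2.5% and 97.5% quantiles and split-chain R-hat for each
#' column of a set of MCMC draws.
#'
#' @param draws list of iterations x parameters matrices (one per chain)
#'   with common column names, or a single matrix (R-hat then NA).
#' @return Data frame with columns \code{parameter, mean, sd, q2.5,
#'   q97.5, rhat}.
#' @export
summarize_draws <- function(draws) {
  if (is.matrix(draws)) draws <- list(draws)
  all_d <- do.call(rbind, draws)
  qs <- apply(all_d, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  rhat <- if (length(draws) >= 2) gelman_rubin(draws) else
    rep(NA_real_, ncol(all_d))
  data.frame(parameter = colnames(all_d),
             mean = colMeans(all_d),
             sd = apply(all_d, 2, stats::sd),
             q2.5 = qs[1, ], q97.5 = qs[2, ],
             rhat = rhat, row.names = NULL)
}

#' Successive-conditional sampler calibration
#'
#' The standard joint-distribution correctness check for MCMC samplers of
#' hierarchical models: if the sampler's transition kernel has the correct
#' stationary distribution, then iterating "simulate data given the
#' current parameters, then advance the parameters by a few MCMC sweeps
#' given those data" leaves the prior invariant, so the chain's marginal
#' parameter distribution must match independent draws from the prior.
#' Systematic disagreement (beyond Monte-Carlo error) indicates a sampler
#' bug.
#'
#' The free parameters are chosen to touch all three likelihood
#' components: the movement scale \code{sigma_move}, the platform-1
#' baseline detection \code{p0}, and the arrival coefficients; the
#' monitored marginals are \code{sigma_move}, \code{p0} and the arrival
#' intercept \code{bg1}. All other parameters are held at the scenario's
#' true values. Uniform priors with the supplied bounds are used both for
#' the reference draws and in the sampler.
#'
#' @param scenario an [scr_scenario()] (keep it small: this runs
#'   \code{n_cycles} complete simulate-plus-MCMC cycles).
#' @param n_cycles number of successive-conditional cycles.
#' @param n_sweeps MCMC sweeps per cycle.
#' @param prior_sigma_move,prior_p0,prior_bg length-2 prior bounds.
#' @param scales named list of fixed random-walk proposal scales for the
#'   free blocks. There is no adaptation inside the calibration cycles (a
#'   changing kernel would invalidate the check), so scales must be large
#'   enough for the chain to traverse the prior in a few sweeps; the
#'   defaults are sized to the default prior widths.
#' @param mode likelihood mode passed to the sampler.
#' @return A list with data frames \code{forward} (independent prior
#'   draws) and \code{chain} (successive-conditional draws), columns
#'   \code{sigma_move, p0, bg1}.
#' @export
successive_conditional_sim <- function(scenario, n_cycles = 300,
                                       n_sweeps = 5,
                                       prior_sigma_move = c(0.5, 4),
                                       prior_p0 = c(0.2, 1),
                                       prior_bg = c(-2, 0),
                                       scales = list(sigma_move.1 = 1.0,
                                                     p0.1.1 = 0.25,
                                                     bg.1 = rep(0.6, 3)),
                                       mode = "latent") {
  stopifnot(scenario$V == 1)
  draw_prior <- function() c(
    sigma_move = stats::runif(1, prior_sigma_move[1], prior_sigma_move[2]),
    p0 = stats::runif(1, prior_p0[1], prior_p0[2]),
    bg1 = stats::runif(1, prior_bg[1], prior_bg[2]),
    bg2 = stats::runif(1, prior_bg[1], prior_bg[2]),
    bg3 = stats::runif(1, prior_bg[1], prior_bg[2]))
  scen_with <- function(th) {
    sc <- scenario
    sc$sigma_move <- th[["sigma_move"]]
    sc$det[[1]]$p0 <- th[["p0"]]
    sc$beta_gamma <- matrix(th[c("bg1", "bg2", "bg3")], 3, 1)
    sc
  }
  fixed <- list(beta = scenario$beta,
                bp = scenario$beta_phi,
                det_sigma = vapply(scenario$det, `[[`, numeric(1), "sigma"),
                det_b = vapply(scenario$det, function(p)
                  if (is.null(p$b)) NA_real_ else p$b, numeric(1)))
  priors <- list(sigma_move = prior_sigma_move, p0 = prior_p0,
                 bg = prior_bg)
  forward <- t(replicate(n_cycles, draw_prior()))
  th <- draw_prior()
  chain <- matrix(NA_real_, n_cycles, 5,
                  dimnames = list(NULL, names(th)))
  forms <- vapply(scenario$det, `[[`, character(1), "form")
  for (cy in seq_len(n_cycles)) {
    sc <- scen_with(th)
    sim <- simulate_study(sc)
    dat <- prepare_fit_data(sim$study, sc$M, quad_m = 1)
    init <- default_init(dat, forms)
    init$beta <- sc$beta
    init$sigma_move <- th[["sigma_move"]]
    init$det <- sc$det
    init$bg <- sc$beta_gamma
    init$bp <- sc$beta_phi
    # start latent states at the truth just simulated: together with the
    # data they form the current joint state of the calibration chain
    st <- sampler_setup(dat, forms, mode, priors = priors, fixed = fixed,
                        init = init, init_latent = truth_latent(sim, dat),
                        scales = scales)
    st$try_win <- st$acc_win <- st$tries
    for (sw in seq_len(n_sweeps)) sampler_sweep(st, dat)
    th <- c(sigma_move = st$par$sigma_move[1],
            p0 = st$par$det[[1]]$p0[1],
            bg1 = st$par$bg[1, 1], bg2 = st$par$bg[2, 1],
            bg3 = st$par$bg[3, 1])
    chain[cy, ] <- th
  }
  keep <- c("sigma_move", "p0", "bg1")
  list(forward = as.data.frame(forward)[keep],
       chain = as.data.frame(chain)[keep])
}

# map simulator truth (simulator indexing) onto the fitting order, where
# observed individuals come first; returns the complete latent state
truth_latent <- function(sim, dat) {
  tz <- sim$truth
  Mtot <- nrow(tz$z)
  perm <- c(tz$sim_id, setdiff(seq_len(Mtot), tz$sim_id))
  inv <- match(seq_len(Mtot), perm)
  Upix <- array(NA_integer_, dim = c(dat$M, dat$Kmax, dat$Tt))
  Ux <- Uy <- array(NA_real_, dim = c(dat$M, dat$Kmax, dat$Tt))
  loc <- tz$locations[tz$locations$detected == 0, , drop = FALSE]
  if (nrow(loc)) {
    idx <- cbind(inv[loc$individual], loc$k, loc$t)
    Upix[idx] <- loc$pixel
    Ux[idx] <- loc$x
    Uy[idx] <- loc$y_coord
  }
  list(group = tz$group[perm], z = tz$z[perm, , drop = FALSE],
       s = tz$s[perm, , drop = FALSE], Upix = Upix, Ux = Ux, Uy = Uy)
}
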