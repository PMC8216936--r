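# Parameter-block Metropolis updates and the user-facing fitting function.

make_blocks <- function(dat, forms, fixed = NULL, scales = NULL) {
  fx <- function(nm) !is.null(fixed) && !is.null(fixed[[nm]])
  blocks <- list()
  add <- function(name, kind, get, set, prior, scale, v = NA, pl = NA) {
    blocks[[name]] <<- list(name = name, kind = kind, get = get, set = set,
                            prior = prior, scale = scale, v = v, pl = pl)
  }
  if (!fx("beta"))
    add("beta", "beta",
        function(p) p$beta,
        function(p, x) { p$beta <- x; p },
        "beta", rep(0.08, dat$Jp))
  for (v in seq_len(dat$V)) {
    vv <- v
    if (!fx("sigma_move"))
      add(paste0("sigma_move.", v), "sigma_move",
          local({ v <- vv; function(p) p$sigma_move[v] }),
          local({ v <- vv; function(p, x) { p$sigma_move[v] <- x; p } }),
          "sigma_move", dat$diam / 40, v = v)
    if (!fx("bg"))
      add(paste0("bg.", v), "bg",
          local({ v <- vv; function(p) p$bg[, v] }),
          local({ v <- vv; function(p, x) { p$bg[, v] <- x; p } }),
          "bg", rep(0.25, 3), v = v)
    if (!fx("bp"))
      add(paste0("bp.", v), "bp",
          local({ v <- vv; function(p) p$bp[, v] }),
          local({ v <- vv; function(p, x) { p$bp[, v] <- x; p } }),
          "bp", rep(0.25, 2), v = v)
  }
  for (pl in seq_along(forms)) {
    pp <- pl
    if (!fx("det_p0")) for (v in seq_len(dat$V)) {
      vv <- v
      add(paste0("p0.", pl, ".", v), "det",
          local({ pl <- pp; v <- vv; function(p) p$det[[pl]]$p0[v] }),
          local({ pl <- pp; v <- vv
                  function(p, x) { p$det[[pl]]$p0[v] <- x; p } }),
          "p0", 0.06, v = v, pl = pl)
    }
    if (!fx("det_sigma"))
      add(paste0("det_sigma.", pl), "det",
          local({ pl <- pp; function(p) p$det[[pl]]$sigma }),
          local({ pl <- pp; function(p, x) { p$det[[pl]]$sigma <- x; p } }),
          "det_sigma", dat$diam / 80, pl = pl)
    if (forms[pl] == "hr" && !fx("det_b"))
      add(paste0("det_b.", pl), "det",
          local({ pl <- pp; function(p) p$det[[pl]]$b }),
          local({ pl <- pp; function(p, x) { p$det[[pl]]$b <- x; p } }),
          "b", 0.25, pl = pl)
  }
  if (!is.null(scales))
    for (nm in intersect(names(scales), names(blocks)))
      blocks[[nm]]$scale <- scales[[nm]]
  blocks
}

# log-likelihood of the component a block touches, under parameters `par`
# with caches `cc` (a list with the matrices the component needs)
block_ll <- function(st, dat, bl, par, cc) {
  switch(bl$kind,
    beta = {
      ll <- ll_s_prior(cc$logpiD, st$s)
      if (st$marginal)
        ll + ll_movdet_marg(par, cc$Mlog, cc$Alog, st, dat)
      else
        ll + ll_mov_latent(cc$Mlog, st, dat)
    },
    sigma_move = {
      if (st$marginal)
        ll_movdet_marg(par, cc$Mlog, cc$Alog, st, dat, groups = bl$v)
      else
        ll_mov_latent(cc$Mlog, st, dat, groups = bl$v)
    },
    det = {
      if (st$marginal)
        ll_movdet_marg(par, cc$Mlog, cc$Alog, st, dat)
      else
        ll_det_latent(par, st, dat)
    },
    bg = ,
    bp = {
      gp <- cc$gp
      ll_z_chain(gp$Gam, gp$Phi, st$z, st$group, groups = bl$v)
    })
}

# caches needed to evaluate a block under parameters `par`; reuse = the
# current sampler caches (for the current parameter value)
block_caches <- function(st, dat, bl, par, reuse = FALSE) {
  if (reuse) {
    return(list(logpiD = st$logpiD, Mlog = st$Mlog, Alog = st$Alog,
                gp = list(Gam = st$Gam, Phi = st$Phi)))
  }
  switch(bl$kind,
    beta = {
      sm <- space_mats(par, dat, st$marginal)
      cc <- list(logpiD = sm$logpiD, eta = sm$eta, Mlog = sm$Mlog,
                 Pmov = sm$Pmov)
      if (st$marginal)
        cc$Alog <- alog_mats(sm$Pmov, st$Pbar, dat)
      cc
    },
    sigma_move = {
      v <- bl$v
      Mlog <- st$Mlog
      Mlog[[v]] <- lapply(seq_len(dat$Tt), function(t)
        log_movement_matrix(dat$D2, st$eta[, t], par$sigma_move[v]))
      cc <- list(Mlog = Mlog)
      if (st$marginal) {
        Pmov <- st$Pmov
        Pmov[[v]] <- lapply(Mlog[[v]], exp)
        cc$Pmov <- Pmov
        cc$Alog <- alog_mats(Pmov, st$Pbar, dat)
      }
      cc
    },
    det = {
      cc <- list(Mlog = st$Mlog)
      if (st$marginal) {
        cc$Pbar <- pbar_mats(par, dat)
        cc$Alog <- alog_mats(st$Pmov, cc$Pbar, dat)
      }
      cc
    },
    bg = ,
    bp = list(gp = gam_phi_mats(par, dat)))
}

# adopt a block's proposed parameters and caches as current
block_accept <- function(st, dat, bl, par, cc) {
  st$par <- par
  switch(bl$kind,
    beta = {
      st$logpiD <- cc$logpiD; st$eta <- cc$eta; st$Mlog <- cc$Mlog
      if (st$marginal) { st$Pmov <- cc$Pmov; st$Alog <- cc$Alog }
    },
    sigma_move = {
      st$Mlog <- cc$Mlog
      if (st$marginal) { st$Pmov <- cc$Pmov; st$Alog <- cc$Alog }
    },
    det = {
      if (st$marginal) { st$Pbar <- cc$Pbar; st$Alog <- cc$Alog }
    },
    bg = ,
    bp = { st$Gam <- cc$gp$Gam; st$Phi <- cc$gp$Phi })
  invisible()
}

mh_block <- function(st, dat, bl) {
  cur <- bl$get(st$par)
  prop <- cur + stats::rnorm(length(cur), 0, bl$scale)
  st$try_win[bl$name] <- st$try_win[bl$name] + 1
  st$tries[bl$name] <- st$tries[bl$name] + 1
  pr <- st$priors[[bl$prior]]
  if (any(prop < pr[1] | prop > pr[2])) return(invisible())
  par_new <- bl$set(st$par, prop)
  cc_cur <- block_caches(st, dat, bl, st$par, reuse = TRUE)
  cc_new <- block_caches(st, dat, bl, par_new)
  ll_cur <- block_ll(st, dat, bl, st$par, cc_cur)
  ll_new <- block_ll(st, dat, bl, par_new, cc_new)
  if (log(stats::runif(1)) < ll_new - ll_cur) {
    block_accept(st, dat, bl, par_new, cc_new)
    st$acc_win[bl$name] <- st$acc_win[bl$name] + 1
    st$accept[bl$name] <- st$accept[bl$name] + 1
  }
  invisible()
}

# one full Metropolis-within-Gibbs sweep over parameters and latent states
sampler_sweep <- function(st, dat) {
  for (bl in st$blocks) mh_block(st, dat, bl)
  update_group(st, dat)
  update_s(st, dat)
  if (!st$marginal) update_u(st, dat)
  update_z(st, dat)
  invisible()
}

# proposal-scale adaptation (burn-in only): nudge each block's scale
# toward a 0.2-0.5 acceptance band
adapt_scales <- function(st) {
  for (nm in names(st$blocks)) {
    if (st$try_win[nm] == 0) next
    rate <- st$acc_win[nm] / st$try_win[nm]
    st$blocks[[nm]]$scale <- st$blocks[[nm]]$scale *
      exp(0.7 * (rate - 0.35))
    st$try_win[nm] <- st$acc_win[nm] <- 0
  }
  invisible()
}

flatten_par <- function(st, dat, cov_names, forms) {
  p <- st$par
  out <- c(stats::setNames(p$beta, paste0("beta.", cov_names)),
           stats::setNames(p$sigma_move,
                           paste0("sigma_move.", seq_len(dat$V))))
  for (pl in seq_along(forms)) {
    out <- c(out,
             stats::setNames(rep_len(p$det[[pl]]$p0, dat$V),
                             paste0("p0.", pl, ".", seq_len(dat$V))),
             stats::setNames(p$det[[pl]]$sigma, paste0("det_sigma.", pl)))
    if (forms[pl] == "hr")
      out <- c(out, stats::setNames(p$det[[pl]]$b, paste0("det_b.", pl)))
  }
  for (v in seq_len(dat$V))
    out <- c(out,
             stats::setNames(p$bg[, v], paste0("bg", 1:3, ".", v)),
             stats::setNames(p$bp[, v], paste0("bp", 1:2, ".", v)))
  if (dat$V > 1)
    out <- c(out, stats::setNames(st$pi_group,
                                  paste0("piGroup.", seq_len(dat$V))))
  out
}

derived_quants <- function(st, dat) {
  N <- derive_abundance(st$z)
  R <- derive_recruits(st$z)
  ever <- apply(st$z, 1, max) > 0
  out <- c(stats::setNames(N, paste0("N.", seq_len(dat$Tt))),
           stats::setNames(R, paste0("R.", seq_len(dat$Tt))),
           Nsuper = sum(ever))
  if (dat$V > 1) {
    for (v in seq_len(dat$V))
      out[paste0("Nsuper.", v)] <- sum(ever & st$group == v)
  }
  out
}

#' Fit the open-population line-transect SCR model
#'
#' Metropolis-within-Gibbs sampler for the full hierarchical model:
#' random-walk Metropolis blocks for the habitat coefficients, movement
#' scales, detection parameters and dynamics coefficients (with proposal
#' scales adapted toward a 0.2-0.5 acceptance band during burn-in, then
#' frozen), and Gibbs or joint Metropolis updates for the latent presence
#' states, activity centers, occasion locations and group memberships.
#'
#' Two likelihood treatments of the latent occasion locations of present
#' but undetected individuals are available. The default (\code{"latent"})
#' samples an explicit location for every such individual-occasion, exactly
#' as the hierarchical model is written. The \code{"marginalized"} option
#' instead integrates locations out of the likelihood,
#' P(undetected | s) = sum_g pi_movement_g (1 - pbar_g), where pbar_g
#' approximates the within-pixel average detection probability by an
#' m-point quadrature (\code{quad_m}; 1 = pixel center, 2 = a 2 x 2 rule).
#' Marginalization is a large runtime lever on detection-parameter updates
#' and mixes faster in sparse data; the two options agree in posterior
#' means up to the quadrature approximation, which is small whenever the
#' detection scale exceeds the pixel side.
#'
#' Uniform priors are used for all parameters; bounds are configurable via
#' \code{priors} (defaults: coefficients (-10, 10); movement and detection
#' scales (0, state-space diameter); hazard-rate shape (1, 50); baselines
#' p0 (0, 1)).
#'
#' @param study an \code{scr_study} (from [simulate_study()] or
#'   [read_study()]).
#' @param M augmented population size (see [augment_histories()]).
#' @param n_iter,n_burnin,n_chains,thin MCMC run settings; kept draws are
#'   \code{(n_iter - n_burnin) / thin} per chain.
#' @param mode \code{"latent"} (default) or \code{"marginalized"}.
#' @param quad_m within-pixel quadrature points per axis for the
#'   marginalized likelihood (1 or 2).
#' @param forms detection-function form per platform ("hn" or "hr");
#'   default half-normal for every platform.
#' @param priors named list overriding prior bounds (names: beta, bg, bp,
#'   sigma_move, det_sigma, b, p0).
#' @param init optional initial parameter list (as built by the sampler:
#'   elements beta, sigma_move, det, bg, bp, a).
#' @param fixed optional named list of parameters to hold fixed (names:
#'   beta, sigma_move, bg, bp, det_p0, det_sigma, det_b).
#' @param seed integer seed; chain c uses \code{seed + c - 1}.
#' @param adapt_interval proposal-adaptation window (iterations) during
#'   burn-in.
#' @param monitor_rd accumulate the posterior mean realized-density
#'   surface.
#' @param verbose print progress.
#' @return An object of class \code{"scr_fit"}: list with \code{draws}
#'   (one iterations x parameters matrix per chain, including derived
#'   N_t, R_t and superpopulation size), \code{accept} (per-block
#'   acceptance rates), \code{rd_mean} (G x T posterior-mean realized
#'   density, if monitored), and run metadata.
#' @seealso [summary.scr_fit()], [gelman_rubin()]
#' @export
scr_fit <- function(study, M, n_iter = 2000, n_burnin = 1000,
                    n_chains = 2, thin = 1,
                    mode = c("latent", "marginalized"), quad_m = 1,
                    forms = NULL, priors = NULL, init = NULL,
                    fixed = NULL, seed = NULL, adapt_interval = 50,
                    monitor_rd = TRUE, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n_iter > n_burnin, n_burnin >= 0)
  dat <- prepare_fit_data(study, M, quad_m)
  if (is.null(forms))
    forms <- rep("hn", length(dat$platforms))
  cov_names <- dimnames(study$X)[[2]]
  n_keep <- floor((n_iter - n_burnin) / thin)
  draws <- vector("list", n_chains)
  accepts <- vector("list", n_chains)
  rd_sum <- if (monitor_rd) matrix(0, dat$G, dat$Tt) else NULL
  rd_n <- 0
  for (ch in seq_len(n_chains)) {
    if (!is.null(seed)) set.seed(seed + ch - 1)
    st <- sampler_setup(dat, forms, mode, priors, fixed, init)
    st$try_win <- st$acc_win <- st$tries
    kept <- NULL
    row <- 0
    for (it in seq_len(n_iter)) {
      sampler_sweep(st, dat)
      if (it <= n_burnin && it %% adapt_interval == 0) adapt_scales(st)
      if (it == n_burnin) {  # freeze scales, reset acceptance accounting
        st$tries[] <- 0; st$accept[] <- 0
      }
      if (it > n_burnin && (it - n_burnin) %% thin == 0) {
        vals <- c(flatten_par(st, dat, cov_names, forms),
                  derived_quants(st, dat))
        if (is.null(kept))
          kept <- matrix(NA_real_, n_keep, length(vals),
                         dimnames = list(NULL, names(vals)))
        row <- row + 1
        kept[row, ] <- vals
        if (monitor_rd) {
          for (t in seq_len(dat$Tt))
            rd_sum[, t] <- rd_sum[, t] +
              realized_density(st$z, st$s, dat$grid, t)
          rd_n <- rd_n + 1
        }
      }
      if (verbose && it %% 500 == 0)
        message(sprintf("chain %d iteration %d / %d", ch, it, n_iter))
    }
    draws[[ch]] <- kept[seq_len(row), , drop = FALSE]
    accepts[[ch]] <- ifelse(st$tries > 0, st$accept / st$tries, NA)
  }
  structure(list(
    draws = draws, accept = accepts,
    rd_mean = if (monitor_rd) rd_sum / max(rd_n, 1) else NULL,
    M = M, mode = mode, quad_m = quad_m, forms = forms,
    n_iter = n_iter, n_burnin = n_burnin, thin = thin, seed = seed,
    cov_names = cov_names, T_periods = dat$Tt, G = dat$G, n = dat$n,
    V = dat$V
  ), class = "scr_fit")
}

#' @export
print.scr_fit <- function(x, ...) {
  cat(sprintf(
    "Open SCR line-transect fit: %d chains x %d kept draws, M = %d (%s)\n",
    length(x$draws), nrow(x$draws[[1]]), x$M, x$mode))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' Posterior mean, sd, the 2.5% and 97.5% quantiles (a 95% credible
#' interval), and the split-chain Gelman-Rubin statistic for every
#' parameter and derived quantity.
#'
#' @param object an \code{scr_fit}.
#' @param ... unused.
#' @return A data frame, one row per monitored quantity.
#' @export
summary.scr_fit <- function(object, ...) {
  summarize_draws(object$draws)
}
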