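# Latent-state updates and the Metropolis-within-Gibbs sweep. The sampler
# state `st` is an environment carrying current parameters, cached
# matrices, and latent states; updates mutate it in place.

sampler_setup <- function(dat, forms, mode = "latent", priors = NULL,
                          fixed = NULL, init = NULL, init_latent = NULL,
                          scales = NULL) {
  st <- new.env(parent = emptyenv())
  st$mode <- mode
  st$marginal <- mode == "marginalized"
  pr <- default_priors(dat)
  if (!is.null(priors)) pr[names(priors)] <- priors
  st$priors <- pr
  par <- if (is.null(init)) default_init(dat, forms) else init
  par <- apply_fixed(par, fixed, dat)
  st$par <- par
  st$fixed <- fixed

  sm <- space_mats(par, dat, st$marginal)
  st$eta <- sm$eta; st$logpiD <- sm$logpiD; st$Mlog <- sm$Mlog
  if (st$marginal) {
    st$Pmov <- sm$Pmov
    st$Pbar <- pbar_mats(par, dat)
    st$Alog <- alog_mats(st$Pmov, st$Pbar, dat)
  }
  gp <- gam_phi_mats(par, dat)
  st$Gam <- gp$Gam; st$Phi <- gp$Phi
  st$pi_group <- pi_group_from_a(par$a)

  if (is.null(init_latent)) {
    st$group <- ifelse(is.na(dat$group_known),
                       sample.int(dat$V, dat$M, replace = TRUE),
                       dat$group_known)
    st$z <- matrix(0L, dat$M, dat$Tt)
    st$z[dat$obs_t] <- 1L
    st$z[!dat$obs_t] <- stats::rbinom(sum(!dat$obs_t), 1, 0.4)
    st$s <- matrix(sample.int(dat$G, dat$M * dat$Tt, replace = TRUE),
                   dat$M, dat$Tt)
  } else {
    st$group <- init_latent$group
    st$z <- init_latent$z
    st$s <- init_latent$s
    st$z[dat$obs_t] <- 1L
  }
  st$Upix <- array(NA_integer_, dim = c(dat$M, dat$Kmax, dat$Tt))
  st$Ux <- st$Uy <- st$mind <- st$plat <-
    array(NA_real_, dim = c(dat$M, dat$Kmax, dat$Tt))
  if (!st$marginal) {
    if (!is.null(init_latent) && !is.null(init_latent$Upix)) {
      st$Upix <- init_latent$Upix
      st$Ux <- init_latent$Ux; st$Uy <- init_latent$Uy
      refresh_latent_dist(st, dat)
    } else {
      for (t in seq_len(dat$Tt)) draw_latent_locations(
        st, dat, t, which(st$z[, t] == 1))
    }
  }

  st$blocks <- make_blocks(dat, forms, fixed, scales)
  st$accept <- stats::setNames(numeric(length(st$blocks)),
                               names(st$blocks))
  st$tries <- st$try_win <- st$acc_win <- st$accept
  st
}

# draw fresh latent locations from the movement prior for individuals
# `ids` on all effort occasions of period t (used at initialization and
# when z flips to 1); overwrites latent entries only (observed occasions
# keep their data)
draw_latent_locations <- function(st, dat, t, ids) {
  if (!length(ids)) return(invisible())
  half <- dat$grid$side / 2
  for (k in seq_len(dat$K[t])) {
    if (!dat$eff[k, t]) next
    lat <- ids[!dat$y[ids, k, t]]
    if (!length(lat)) next
    for (v in unique(st$group[lat])) {
      sel <- lat[st$group[lat] == v]
      lw <- st$Mlog[[v]][[t]][st$s[sel, t], , drop = FALSE]
      pix <- gumbel_argmax(lw)
      st$Upix[sel, k, t] <- pix
      st$Ux[sel, k, t] <- dat$grid$centers[pix, 1] +
        stats::runif(length(sel), -half, half)
      st$Uy[sel, k, t] <- dat$grid$centers[pix, 2] +
        stats::runif(length(sel), -half, half)
      md <- min_distance_to_transects(st$Ux[sel, k, t], st$Uy[sel, k, t],
                                      dat$occ[[t]][[k]])
      st$mind[sel, k, t] <- md$distance
      st$plat[sel, k, t] <- dat$occ[[t]][[k]]$platform[md$segment]
    }
  }
}

# recompute mindist/platform caches for already-set latent coordinates
refresh_latent_dist <- function(st, dat) {
  for (t in seq_len(dat$Tt)) for (k in seq_len(dat$K[t])) {
    if (!dat$eff[k, t]) next
    sel <- which(!is.na(st$Upix[, k, t]))
    if (!length(sel)) next
    md <- min_distance_to_transects(st$Ux[sel, k, t], st$Uy[sel, k, t],
                                    dat$occ[[t]][[k]])
    st$mind[sel, k, t] <- md$distance
    st$plat[sel, k, t] <- dat$occ[[t]][[k]]$platform[md$segment]
  }
  invisible()
}

# ---- latent-state updates --------------------------------------------

# activity centers: Gibbs draw per individual per period
update_s <- function(st, dat) {
  for (t in seq_len(dat$Tt)) {
    absent <- which(st$z[, t] == 0)
    if (length(absent)) {
      pd <- exp(st$logpiD[, t])
      st$s[absent, t] <- sample.int(dat$G, length(absent), replace = TRUE,
                                    prob = pd)
    }
    pres <- which(st$z[, t] == 1)
    if (!length(pres)) next
    for (v in unique(st$group[pres])) {
      ids <- pres[st$group[pres] == v]
      lw <- matrix(st$logpiD[, t], dat$G, length(ids))
      for (k in seq_len(dat$K[t])) {
        if (!dat$eff[k, t]) next
        det <- dat$y[ids, k, t]
        if (st$marginal) {
          if (any(!det))
            lw[, !det] <- lw[, !det] + st$Alog[[v]][[t]][, k]
          if (any(det))
            lw[, det] <- lw[, det] +
              st$Mlog[[v]][[t]][, dat$upix_obs[ids[det], k, t],
                                drop = FALSE]
        } else {
          pix <- ifelse(det, dat$upix_obs[ids, k, t], st$Upix[ids, k, t])
          lw <- lw + st$Mlog[[v]][[t]][, pix, drop = FALSE]
        }
      }
      st$s[ids, t] <- gumbel_argmax(t(lw))
    }
  }
  invisible()
}

# latent occasion locations (latent mode): independence MH with the
# movement prior as proposal; acceptance ratio is the (1 - p) likelihood
# ratio of not being detected there
update_u <- function(st, dat) {
  half <- dat$grid$side / 2
  for (t in seq_len(dat$Tt)) {
    pres <- which(st$z[, t] == 1)
    if (!length(pres)) next
    for (k in seq_len(dat$K[t])) {
      if (!dat$eff[k, t]) next
      ids <- pres[!dat$y[pres, k, t]]
      if (!length(ids)) next
      pix_new <- integer(length(ids))
      for (v in unique(st$group[ids])) {
        sel <- st$group[ids] == v
        lw <- st$Mlog[[v]][[t]][st$s[ids[sel], t], , drop = FALSE]
        pix_new[sel] <- gumbel_argmax(lw)
      }
      xn <- dat$grid$centers[pix_new, 1] +
        stats::runif(length(ids), -half, half)
      yn <- dat$grid$centers[pix_new, 2] +
        stats::runif(length(ids), -half, half)
      md <- min_distance_to_transects(xn, yn, dat$occ[[t]][[k]])
      pn <- dat$occ[[t]][[k]]$platform[md$segment]
      p_new <- p_vec(md$distance, pn, st$group[ids], st$par, dat)
      p_old <- p_vec(st$mind[ids, k, t], st$plat[ids, k, t],
                     st$group[ids], st$par, dat)
      acc <- log(stats::runif(length(ids))) < log1p(-p_new) - log1p(-p_old)
      w <- ids[acc]
      if (length(w)) {
        st$Upix[w, k, t] <- pix_new[acc]
        st$Ux[w, k, t] <- xn[acc]; st$Uy[w, k, t] <- yn[acc]
        st$mind[w, k, t] <- md$distance[acc]
        st$plat[w, k, t] <- pn[acc]
      }
    }
  }
  invisible()
}

# prior log-odds of z[i, t] = 1 vs 0 given the individual's neighbors
z_prior_logodds <- function(st, dat, t, ids) {
  gv <- st$group[ids]
  if (t == 1) {
    pr1 <- st$Gam[1, gv]
  } else {
    pr1 <- ifelse(st$z[ids, t - 1] == 1, st$Phi[t - 1, gv], st$Gam[t, gv])
  }
  lo <- log(pr1) - log1p(-pr1)
  if (t < dat$Tt) {
    znext <- st$z[ids, t + 1]
    p_if1 <- ifelse(znext == 1, st$Phi[t, gv], 1 - st$Phi[t, gv])
    p_if0 <- ifelse(znext == 1, st$Gam[t + 1, gv], 1 - st$Gam[t + 1, gv])
    lo <- lo + log(p_if1) - log(p_if0)
  }
  lo
}

# presence states: exact Gibbs in marginalized mode; in latent mode a
# joint (z, U) Metropolis flip with the movement prior as the U proposal
update_z <- function(st, dat) {
  half <- dat$grid$side / 2
  for (t in seq_len(dat$Tt)) {
    cand <- which(!dat$obs_t[, t])
    if (!length(cand)) next
    lo <- z_prior_logodds(st, dat, t, cand)
    if (st$marginal) {
      lp_nodet <- numeric(length(cand))
      for (k in seq_len(dat$K[t])) {
        if (!dat$eff[k, t]) next
        for (v in unique(st$group[cand])) {
          sel <- st$group[cand] == v
          lp_nodet[sel] <- lp_nodet[sel] +
            st$Alog[[v]][[t]][cbind(st$s[cand[sel], t], k)]
        }
      }
      st$z[cand, t] <- stats::rbinom(length(cand), 1,
                                     stats::plogis(lo + lp_nodet))
      next
    }
    # snapshot: every candidate gets exactly one flip proposal, its
    # direction set by the state at the start of the period's update
    cur1 <- st$z[cand, t] == 1
    ones <- cand[cur1]
    zeros <- cand[!cur1]
    if (length(ones)) {
      lp <- numeric(length(ones))
      for (k in seq_len(dat$K[t])) {
        if (!dat$eff[k, t]) next
        p <- p_vec(st$mind[ones, k, t], st$plat[ones, k, t],
                   st$group[ones], st$par, dat)
        lp <- lp + log1p(-p)
      }
      acc <- log(stats::runif(length(ones))) <
        -lo[match(ones, cand)] - lp
      drop_ids <- ones[acc]
      if (length(drop_ids)) {
        st$z[drop_ids, t] <- 0L
        st$Upix[drop_ids, , t] <- NA_integer_
        st$Ux[drop_ids, , t] <- st$Uy[drop_ids, , t] <- NA_real_
        st$mind[drop_ids, , t] <- st$plat[drop_ids, , t] <- NA_real_
      }
    }
    if (length(zeros)) {
      prop <- list()
      lp <- numeric(length(zeros))
      for (k in seq_len(dat$K[t])) {
        if (!dat$eff[k, t]) { prop[k] <- list(NULL); next }
        pix <- integer(length(zeros))
        for (v in unique(st$group[zeros])) {
          sel <- st$group[zeros] == v
          lw <- st$Mlog[[v]][[t]][st$s[zeros[sel], t], , drop = FALSE]
          pix[sel] <- gumbel_argmax(lw)
        }
        xn <- dat$grid$centers[pix, 1] +
          stats::runif(length(zeros), -half, half)
        yn <- dat$grid$centers[pix, 2] +
          stats::runif(length(zeros), -half, half)
        md <- min_distance_to_transects(xn, yn, dat$occ[[t]][[k]])
        pn <- dat$occ[[t]][[k]]$platform[md$segment]
        p <- p_vec(md$distance, pn, st$group[zeros], st$par, dat)
        lp <- lp + log1p(-p)
        prop[[k]] <- list(pix = pix, x = xn, y = yn, mind = md$distance,
                          plat = pn)
      }
      acc <- log(stats::runif(length(zeros))) < lo[match(zeros, cand)] + lp
      add_ids <- which(acc)
      if (length(add_ids)) {
        st$z[zeros[add_ids], t] <- 1L
        for (k in seq_len(dat$K[t])) {
          if (!dat$eff[k, t]) next
          w <- zeros[add_ids]
          st$Upix[w, k, t] <- prop[[k]]$pix[add_ids]
          st$Ux[w, k, t] <- prop[[k]]$x[add_ids]
          st$Uy[w, k, t] <- prop[[k]]$y[add_ids]
          st$mind[w, k, t] <- prop[[k]]$mind[add_ids]
          st$plat[w, k, t] <- prop[[k]]$plat[add_ids]
        }
      }
    }
  }
  invisible()
}

# latent group membership: Gibbs over the V groups for individuals with
# unknown labels; then the gamma weights a_v from their full conditional
# (Dirichlet(1 + counts) via independent gammas)
update_group <- function(st, dat) {
  if (dat$V > 1) {
    unk <- which(is.na(dat$group_known))
    if (length(unk)) {
      lw <- matrix(log(st$pi_group), length(unk), dat$V, byrow = TRUE)
      for (v in seq_len(dat$V)) {
        gsub <- rep(v, length(unk))
        lw[, v] <- lw[, v] +
          ll_z_chain_vec(st$Gam, st$Phi, st$z[unk, , drop = FALSE], v)
        lw[, v] <- lw[, v] + ll_i_movdet_group(st, dat, unk, v)
      }
      st$group[unk] <- gumbel_argmax(lw)
    }
  }
  counts <- tabulate(st$group, nbins = dat$V)
  st$par$a <- stats::rgamma(dat$V, shape = 1 + counts, rate = 1)
  st$pi_group <- pi_group_from_a(st$par$a)
  invisible()
}

# per-individual z-path log-likelihood under group v's dynamics
ll_z_chain_vec <- function(Gam, Phi, z, v) {
  Tt <- ncol(z)
  pr1 <- Gam[1, v]
  ll <- ifelse(z[, 1] == 1, log(pr1), log1p(-pr1))
  for (t in 2:Tt) {
    pr <- ifelse(z[, t - 1] == 1, Phi[t - 1, v], Gam[t, v])
    ll <- ll + ifelse(z[, t] == 1, log(pr), log1p(-pr))
  }
  ll
}

# per-individual movement + detection log-likelihood under group v
ll_i_movdet_group <- function(st, dat, ids, v) {
  ll <- numeric(length(ids))
  for (t in seq_len(dat$Tt)) {
    pres <- st$z[ids, t] == 1
    if (!any(pres)) next
    ii <- ids[pres]
    for (k in seq_len(dat$K[t])) {
      if (!dat$eff[k, t]) next
      det <- dat$y[ii, k, t]
      if (st$marginal) {
        add <- numeric(length(ii))
        if (any(!det))
          add[!det] <- st$Alog[[v]][[t]][cbind(st$s[ii[!det], t], k)]
        if (any(det)) {
          add[det] <- st$Mlog[[v]][[t]][cbind(st$s[ii[det], t],
                                              dat$upix_obs[ii[det], k, t])] +
            log(p_vec(dat$mind_obs[ii[det], k, t],
                      dat$plat_obs[ii[det], k, t], v, st$par, dat))
        }
      } else {
        pix <- ifelse(det, dat$upix_obs[ii, k, t], st$Upix[ii, k, t])
        mind <- ifelse(det, dat$mind_obs[ii, k, t], st$mind[ii, k, t])
        plat <- ifelse(det, dat$plat_obs[ii, k, t], st$plat[ii, k, t])
        p <- p_vec(mind, plat, v, st$par, dat)
        add <- st$Mlog[[v]][[t]][cbind(st$s[ii, t], pix)] +
          ifelse(det, log(p), log1p(-p))
      }
      ll[pres] <- ll[pres] + add
    }
  }
  ll
}
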