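# Sampler internals: data preparation, likelihood components, latent-state
# and parameter-block updates. The sampler state lives in an environment
# (st) so latent updates can mutate in place; all user-facing access goes
# through scr_fit().

# ---- data preparation -------------------------------------------------

prepare_fit_data <- function(study, M, quad_m = 1) {
  grid <- study$grid
  Tt <- study$T_periods
  K <- study$K
  Kmax <- max(K)
  aug <- suppressWarnings(augment_histories(study, M))
  diam <- sqrt((grid$n_x * grid$side)^2 + (grid$n_y * grid$side)^2)

  occ <- vector("list", Tt)
  quad <- vector("list", Tt)
  qpts <- quad_points(grid, quad_m)
  for (t in seq_len(Tt)) {
    occ[[t]] <- vector("list", K[t])
    quad[[t]] <- vector("list", K[t])
    for (k in seq_len(K[t])) {
      segs <- study$segments[study$segments$t == t & study$segments$k == k,
                             , drop = FALSE]
      if (nrow(segs) == 0) next
      occ[[t]][[k]] <- segs
      Q <- ncol(qpts$x)
      dist <- plat <- matrix(NA_real_, grid$G, Q)
      for (q in seq_len(Q)) {
        md <- min_distance_to_transects(qpts$x[, q], qpts$y[, q], segs)
        dist[, q] <- md$distance
        plat[, q] <- segs$platform[md$segment]
      }
      quad[[t]][[k]] <- list(dist = dist, plat = plat)
    }
  }
  eff <- matrix(FALSE, Kmax, Tt)
  for (t in seq_len(Tt)) for (k in seq_len(K[t]))
    eff[k, t] <- !is.null(occ[[t]][[k]])

  y <- array(FALSE, dim = c(M, Kmax, Tt))
  upix_obs <- array(NA_integer_, dim = c(M, Kmax, Tt))
  mind_obs <- plat_obs <- array(NA_real_, dim = c(M, Kmax, Tt))
  de <- study$detections
  if (nrow(de)) {
    for (r in seq_len(nrow(de))) {
      i <- de$individual[r]; t <- de$t[r]; k <- de$k[r]
      if (!eff[k, t]) stop("detection on an occasion without effort")
      y[i, k, t] <- TRUE
      upix_obs[i, k, t] <- pixel_of_point(de$x[r], de$y[r], grid)
      md <- min_distance_to_transects(de$x[r], de$y[r], occ[[t]][[k]])
      mind_obs[i, k, t] <- md$distance
      plat_obs[i, k, t] <- occ[[t]][[k]]$platform[md$segment]
    }
  }
  obs_t <- apply(y, c(1, 3), any)

  platforms <- sort(unique(study$segments$platform))
  list(grid = grid, G = grid$G, Tt = Tt, K = K, Kmax = Kmax,
       M = M, n = aug$n, V = study$V, group_known = aug$group,
       X = study$X, Jp = dim(study$X)[2],
       D2 = pixel_dist2_matrix(grid), diam = diam,
       time = standardize_time(Tt),
       occ = occ, quad = quad, eff = eff,
       y = y, upix_obs = upix_obs, mind_obs = mind_obs,
       plat_obs = plat_obs, obs_t = obs_t,
       platforms = platforms)
}

# within-pixel quadrature points for the marginalized likelihood:
# m = 1 -> pixel centers; m = 2 -> 2 x 2 midpoints per pixel
quad_points <- function(grid, m) {
  if (m == 1) return(list(x = grid$centers[, 1, drop = FALSE],
                          y = grid$centers[, 2, drop = FALSE]))
  if (m == 2) {
    o <- grid$side / 4
    dx <- c(-o, o, -o, o); dy <- c(-o, -o, o, o)
    return(list(x = outer(grid$centers[, 1], dx, "+"),
                y = outer(grid$centers[, 2], dy, "+")))
  }
  stop("quad_m must be 1 or 2")
}

# ---- parameters -------------------------------------------------------

default_priors <- function(dat) {
  list(beta = c(-10, 10), bg = c(-10, 10), bp = c(-10, 10),
       sigma_move = c(1e-6, dat$diam), det_sigma = c(1e-6, dat$diam),
       b = c(1, 50), p0 = c(0, 1), alpha = c(-10, 10))
}

# detection baseline matrix: V x P
p0_mat <- function(par, dat) {
  P <- length(par$det)
  out <- matrix(NA_real_, dat$V, P)
  for (pl in seq_len(P)) out[, pl] <- rep_len(par$det[[pl]]$p0, dat$V)
  out
}

# detection probability for vectors of distances/platform indices, group a
# vector (recycled); par$det as in det_params()
p_vec <- function(dist, plat, group, par, dat) {
  p <- numeric(length(dist))
  group <- rep_len(group, length(dist))
  p0m <- p0_mat(par, dat)
  for (pl in unique(plat[!is.na(plat)])) {
    pp <- par$det[[pl]]
    for (v in unique(group)) {
      sel <- which(plat == pl & group == v)
      if (!length(sel)) next
      p[sel] <- switch(pp$form,
        hn = p_halfnormal(dist[sel], p0m[v, pl], pp$sigma),
        hr = p_hazardrate(dist[sel], p0m[v, pl], pp$sigma, pp$b))
    }
  }
  p
}

default_init <- function(dat, forms, chain = 1) {
  jit <- function(x, a) x + stats::runif(length(x), -a, a)
  det <- vector("list", length(forms))
  for (pl in seq_along(forms)) {
    det[[pl]] <- list(form = forms[pl],
                      p0 = rep(min(0.95, jit(0.5, 0.1)), dat$V),
                      sigma = jit(dat$diam / 15, dat$diam / 60))
    if (forms[pl] == "hr") det[[pl]]$b <- jit(2.5, 0.3)
  }
  list(beta = jit(rep(0, dat$Jp), 0.1),
       sigma_move = jit(rep(dat$diam / 8, dat$V), dat$diam / 40),
       det = det,
       bg = matrix(jit(rep(c(-1, 0, 0), dat$V), 0.2), 3, dat$V),
       bp = matrix(jit(rep(c(0.5, 0), dat$V), 0.2), 2, dat$V),
       a = rep(1, dat$V))
}

apply_fixed <- function(par, fixed, dat) {
  if (is.null(fixed)) return(par)
  if (!is.null(fixed$beta)) par$beta <- fixed$beta
  if (!is.null(fixed$sigma_move)) par$sigma_move <- fixed$sigma_move
  if (!is.null(fixed$bg)) par$bg <- matrix(fixed$bg, 3, dat$V)
  if (!is.null(fixed$bp)) par$bp <- matrix(fixed$bp, 2, dat$V)
  if (!is.null(fixed$det_sigma))
    for (pl in seq_along(par$det)) par$det[[pl]]$sigma <- fixed$det_sigma[pl]
  if (!is.null(fixed$det_b))
    for (pl in seq_along(par$det))
      if (par$det[[pl]]$form == "hr") par$det[[pl]]$b <- fixed$det_b[pl]
  if (!is.null(fixed$det_p0)) {
    p0 <- fixed$det_p0
    if (!is.matrix(p0)) p0 <- matrix(p0, dat$V, length(par$det))
    for (pl in seq_along(par$det)) par$det[[pl]]$p0 <- p0[, pl]
  }
  par
}

# ---- cached matrices --------------------------------------------------

# movement/density matrices for current beta, sigma_move
space_mats <- function(par, dat, marginal) {
  eta <- sapply(seq_len(dat$Tt),
                function(t) density_linpred(par$beta, dat$X, t))
  eta <- matrix(eta, dat$G, dat$Tt)
  logpiD <- apply(eta, 2, function(e) {
    w <- e - max(e); w - log(sum(exp(w)))
  })
  logpiD <- matrix(logpiD, dat$G, dat$Tt)
  Mlog <- vector("list", dat$V)
  for (v in seq_len(dat$V)) {
    Mlog[[v]] <- vector("list", dat$Tt)
    for (t in seq_len(dat$Tt))
      Mlog[[v]][[t]] <- log_movement_matrix(dat$D2, eta[, t],
                                            par$sigma_move[v])
  }
  out <- list(eta = eta, logpiD = logpiD, Mlog = Mlog)
  if (marginal) {
    out$Pmov <- lapply(Mlog, function(l) lapply(l, exp))
  }
  out
}

# per-occasion pixel-averaged detection probability (marginalized mode):
# Pbar[[t]] is a G x K[t] x V array (NA pages where no effort)
pbar_mats <- function(par, dat) {
  Pbar <- vector("list", dat$Tt)
  for (t in seq_len(dat$Tt)) {
    Pbar[[t]] <- array(NA_real_, dim = c(dat$G, dat$K[t], dat$V))
    for (k in seq_len(dat$K[t])) {
      qd <- dat$quad[[t]][[k]]
      if (is.null(qd)) next
      for (v in seq_len(dat$V)) {
        pq <- p_vec(as.vector(qd$dist), as.vector(qd$plat), v, par, dat)
        Pbar[[t]][, k, v] <- rowMeans(matrix(pq, dat$G))
      }
    }
  }
  Pbar
}

# Alog[[v]][[t]]: G x K[t], log probability of NOT being detected on
# occasion k for an individual with activity center g (movement and
# within-pixel detection integrated out)
alog_mats <- function(Pmov, Pbar, dat) {
  Alog <- vector("list", dat$V)
  for (v in seq_len(dat$V)) {
    Alog[[v]] <- vector("list", dat$Tt)
    for (t in seq_len(dat$Tt)) {
      A <- matrix(NA_real_, dat$G, dat$K[t])
      for (k in seq_len(dat$K[t])) {
        if (!dat$eff[k, t]) next
        A[, k] <- log(Pmov[[v]][[t]] %*% (1 - Pbar[[t]][, k, v]))
      }
      Alog[[v]][[t]] <- A
    }
  }
  Alog
}

gam_phi_mats <- function(par, dat) {
  Gam <- Phi <- NULL
  Gam <- sapply(seq_len(dat$V), function(v) gamma_t(par$bg[, v], dat$time))
  Phi <- sapply(seq_len(dat$V), function(v) phi_t(par$bp[, v], dat$time))
  list(Gam = matrix(Gam, dat$Tt, dat$V), Phi = matrix(Phi, dat$Tt, dat$V))
}

# ---- likelihood components -------------------------------------------

ll_z_chain <- function(Gam, Phi, z, group, groups = NULL) {
  idx <- if (is.null(groups)) seq_len(nrow(z)) else
    which(group %in% groups)
  if (!length(idx)) return(0)
  zz <- z[idx, , drop = FALSE]
  gv <- group[idx]
  Tt <- ncol(z)
  pr1 <- Gam[1, gv]
  ll <- sum(log(ifelse(zz[, 1] == 1, pr1, 1 - pr1)))
  for (t in 2:Tt) {
    pr <- ifelse(zz[, t - 1] == 1, Phi[t - 1, gv], Gam[t, gv])
    ll <- ll + sum(log(ifelse(zz[, t] == 1, pr, 1 - pr)))
  }
  ll
}

# activity-center prior term: all M individuals, every period
ll_s_prior <- function(logpiD, s) {
  sum(logpiD[cbind(as.vector(s),
                   rep(seq_len(ncol(s)), each = nrow(s)))])
}

# occasion-level index of "active" entries: z = 1 and effort; returns a
# data.frame-like list of (i, k, t) with pixel (observed or latent)
active_entries <- function(st, dat, groups = NULL, t_only = NULL) {
  out_i <- out_k <- out_t <- out_pix <- integer(0)
  out_det <- logical(0)
  out_mind <- out_plat <- numeric(0)
  ts <- if (is.null(t_only)) seq_len(dat$Tt) else t_only
  for (t in ts) {
    pres <- which(st$z[, t] == 1)
    if (!is.null(groups)) pres <- pres[st$group[pres] %in% groups]
    if (!length(pres)) next
    for (k in seq_len(dat$K[t])) {
      if (!dat$eff[k, t]) next
      det <- dat$y[pres, k, t]
      pix <- ifelse(det, dat$upix_obs[pres, k, t], st$Upix[pres, k, t])
      mind <- ifelse(det, dat$mind_obs[pres, k, t], st$mind[pres, k, t])
      plat <- ifelse(det, dat$plat_obs[pres, k, t], st$plat[pres, k, t])
      out_i <- c(out_i, pres); out_k <- c(out_k, rep(k, length(pres)))
      out_t <- c(out_t, rep(t, length(pres)))
      out_pix <- c(out_pix, pix); out_det <- c(out_det, det)
      out_mind <- c(out_mind, mind); out_plat <- c(out_plat, plat)
    }
  }
  list(i = out_i, k = out_k, t = out_t, pix = out_pix, det = out_det,
       mind = out_mind, plat = out_plat)
}

# movement term, latent mode: sum over active entries of
# Mlog[group][t][s, pixel]
ll_mov_latent <- function(Mlog, st, dat, groups = NULL) {
  ae <- active_entries(st, dat, groups)
  if (!length(ae$i)) return(0)
  ll <- 0
  for (v in unique(st$group[ae$i])) {
    for (t in unique(ae$t)) {
      sel <- st$group[ae$i] == v & ae$t == t
      if (!any(sel)) next
      ll <- ll + sum(Mlog[[v]][[t]][cbind(st$s[ae$i[sel], t],
                                          ae$pix[sel])])
    }
  }
  ll
}

# detection term, latent mode
ll_det_latent <- function(par, st, dat, groups = NULL) {
  ae <- active_entries(st, dat, groups)
  if (!length(ae$i)) return(0)
  p <- p_vec(ae$mind, ae$plat, st$group[ae$i], par, dat)
  sum(ifelse(ae$det, log(p), log1p(-p)))
}

# combined movement + detection term, marginalized mode
ll_movdet_marg <- function(par, Mlog, Alog, st, dat, groups = NULL) {
  ae <- active_entries(st, dat, groups)
  if (!length(ae$i)) return(0)
  ll <- 0
  gv <- st$group[ae$i]
  for (v in unique(gv)) {
    for (t in unique(ae$t)) {
      sel <- gv == v & ae$t == t
      if (!any(sel)) next
      det <- ae$det[sel]
      ss <- st$s[ae$i[sel], t]
      if (any(det)) {
        ll <- ll + sum(Mlog[[v]][[t]][cbind(ss[det], ae$pix[sel][det])])
        p <- p_vec(ae$mind[sel][det], ae$plat[sel][det], v, par, dat)
        ll <- ll + sum(log(p))
      }
      if (any(!det))
        ll <- ll + sum(Alog[[v]][[t]][cbind(ss[!det], ae$k[sel][!det])])
    }
  }
  ll
}
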