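#' Standardized primary-period index
#'
#' The period indices 1..T centered to mean zero and scaled to unit standard
#' deviation; this is the time covariate entering the arrival and
#' persistence models. By default the population standard deviation
#' (divisor T) is used so the vector has sd exactly 1 in the descriptive
#' sense; set \code{sample_sd = TRUE} for the divisor T - 1 convention.
#'
#' @param T_periods number of primary periods (>= 2).
#' @param sample_sd use the sample rather than population sd.
#' @return Numeric vector of length \code{T_periods}.
#' @export
standardize_time <- function(T_periods, sample_sd = FALSE) {
  if (T_periods < 2) stop("need at least two primary periods")
  t <- seq_len(T_periods)
  ctr <- t - mean(t)
  s <- if (sample_sd) stats::sd(t) else sqrt(mean(ctr^2))
  ctr / s
}

#' Arrival and persistence probabilities
#'
#' Arrival (entry into the study area) probability is a quadratic function
#' of standardized time on the logit scale,
#' \code{logit(gamma_t) = bg1 + bg2 * time_t + bg3 * time_t^2};
#' persistence (remaining in the study area) is linear,
#' \code{logit(phi_t) = bp1 + bp2 * time_t}. For a migratory study area
#' these play the roles recruitment and survival play in a closed range.
#'
#' @param beta_gamma numeric length-3 coefficient vector.
#' @param beta_phi numeric length-2 coefficient vector.
#' @param time_t standardized time value(s), see [standardize_time()].
#' @return Probabilities in (0, 1), same length as \code{time_t}.
#' @export
gamma_t <- function(beta_gamma, time_t) {
  stopifnot(length(beta_gamma) == 3, all(is.finite(beta_gamma)))
  stats::plogis(beta_gamma[1] + beta_gamma[2] * time_t +
                  beta_gamma[3] * time_t^2)
}

#' @rdname gamma_t
#' @export
phi_t <- function(beta_phi, time_t) {
  stopifnot(length(beta_phi) == 2, all(is.finite(beta_phi)))
  stats::plogis(beta_phi[1] + beta_phi[2] * time_t)
}

#' Presence-state transition probability
#'
#' Probability that an individual is in the population at period t given its
#' state at t - 1: an individual present at t - 1 persists with probability
#' \code{phi_prev}; an individual absent at t - 1 enters with probability
#' \code{gamma_t}. At t = 1 every one of the M augmented individuals is in
#' the population with probability gamma_1, the proportion of M present at
#' the first period. Re-entry after departure is allowed and uses the same
#' arrival probability as initial entry.
#'
#' @param z_prev previous presence state, 0/1 (vectorized); use
#'   \code{NULL} for the initial period.
#' @param phi_prev persistence probability at t - 1.
#' @param gamma_t arrival probability at t.
#' @return Probability that z_t = 1.
#' @export
transition_prob <- function(z_prev, phi_prev, gamma_t) {
  if (is.null(z_prev)) return(gamma_t)
  ifelse(z_prev == 1, phi_prev, gamma_t)
}

#' Derived population quantities from the presence matrix
#'
#' `derive_abundance()` gives per-period abundance N_t = sum_i z_{i,t};
#' `derive_recruits()` gives per-period recruitment
#' R_t = sum_i (1 - z_{i,t-1}) z_{i,t} for t >= 2, with R_1 = N_1 reported
#' as initial entry by convention; `superpopulation_size()` counts the
#' individuals ever present during the study.
#'
#' @param z M x T binary matrix of presence states.
#' @return `derive_abundance`: integer vector of length T.
#' @export
derive_abundance <- function(z) {
  z <- as.matrix(z)
  as.integer(colSums(z))
}

#' @rdname derive_abundance
#' @return `derive_recruits`: integer vector of length T (first element
#'   N_1).
#' @export
derive_recruits <- function(z) {
  z <- as.matrix(z)
  if (ncol(z) < 2) stop("recruitment needs at least two primary periods")
  r <- colSums((1 - z[, -ncol(z), drop = FALSE]) * z[, -1, drop = FALSE])
  as.integer(c(sum(z[, 1]), r))
}

#' @rdname derive_abundance
#' @return `superpopulation_size`: integer scalar, number of individuals
#'   with z_{i,t} = 1 for at least one t.
#' @export
superpopulation_size <- function(z) {
  z <- as.matrix(z)
  sum(apply(z, 1, max) > 0)
}
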