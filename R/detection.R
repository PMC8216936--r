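#' Distance-sampling detection functions with estimable intercept
#'
#' Detection probability as a function of \code{mindist}, the distance from
#' an individual's location to the nearest point on the nearest surveyed
#' transect. Unlike conventional distance sampling, the probability of
#' detection on the line, \code{p0}, is an estimable parameter rather than
#' assumed 1 (appropriate for species that may be below the surface, or
#' otherwise unavailable, when the platform passes).
#'
#' `p_halfnormal()`: \code{p0 * exp(-d^2 / (2 sigma^2))}.
#'
#' `p_hazardrate()`: \code{p0 * (1 - exp(-(d / sigma)^-b))}; at d = 0 the
#' exponent diverges and the expression is taken at its limit \code{p0},
#' giving a continuous, strictly decreasing function on d >= 0.
#'
#' @param mindist non-negative distance(s).
#' @param p0 baseline detection probability in (0, 1].
#' @param sigma positive scale parameter (distance units).
#' @param b hazard-rate shape (> 1); larger values give a more pronounced
#'   shoulder near the line.
#' @return Detection probabilities in \code{[0, p0]}.
#' @export
p_halfnormal <- function(mindist, p0, sigma) {
  stopifnot(all(mindist >= 0), p0 >= 0, p0 <= 1, sigma > 0)
  p0 * exp(-mindist^2 / (2 * sigma^2))
}

#' @rdname p_halfnormal
#' @export
p_hazardrate <- function(mindist, p0, sigma, b) {
  stopifnot(all(mindist >= 0), p0 >= 0, p0 <= 1, sigma > 0, b > 1)
  p <- ifelse(mindist == 0, p0, p0 * (1 - exp(-(mindist / sigma)^(-b))))
  p
}

#' Detection probability for a location on an occasion
#'
#' Computes \code{mindist} over the occasion's transect segments, then
#' applies the detection function of the platform that flew the nearest
#' segment, using the baseline \code{p0} of the individual's group. With no
#' survey effort on the occasion the detection probability is zero (an
#' individual cannot be detected when no transects were surveyed).
#'
#' @param x,y location coordinates (vectors, recycled).
#' @param segments data frame of the occasion's segments with columns
#'   \code{x1, y1, x2, y2, platform}; may have zero rows (no effort).
#' @param det_params detection parameters: a list with, per platform index,
#'   \code{form} ("hn" or "hr"), \code{p0} (vector over groups), and
#'   \code{sigma} (plus \code{b} for "hr"). See [det_params()].
#' @param group group index of the individual (default 1).
#' @return Numeric vector of detection probabilities.
#' @export
detection_prob <- function(x, y, segments, det_params, group = 1) {
  segments <- as.data.frame(segments)
  n <- max(length(x), length(y))
  if (nrow(segments) == 0) return(rep(0, n))
  md <- min_distance_to_transects(x, y, segments)
  plat <- segments$platform[md$segment]
  p <- numeric(n)
  for (pl in unique(plat)) {
    sel <- plat == pl
    pp <- det_params[[pl]]
    p[sel] <- switch(pp$form,
      hn = p_halfnormal(md$distance[sel], pp$p0[group], pp$sigma),
      hr = p_hazardrate(md$distance[sel], pp$p0[group], pp$sigma, pp$b),
      stop("unknown detection form: ", pp$form))
  }
  p
}

#' Detection-parameter container
#'
#' Per-platform detection parameters. \code{p0} may be a vector over
#' demographic groups (the shape of the detection function — \code{sigma},
#' \code{b} — is shared across groups; only the baseline differs).
#'
#' @param ... one list per platform, each with elements \code{form}
#'   ("hn" or "hr"), \code{p0}, \code{sigma}, and \code{b} for "hr".
#' @return A list of class \code{"scr_det_params"}.
#' @export
det_params <- function(...) {
  pl <- list(...)
  for (p in pl) {
    stopifnot(p$form %in% c("hn", "hr"), all(p$p0 >= 0), all(p$p0 <= 1),
              p$sigma > 0)
    if (p$form == "hr") stopifnot(p$b > 1)
  }
  structure(pl, class = "scr_det_params")
}

#' Bernoulli observation log-likelihood
#'
#' Log-probability of detection indicators under
#' \code{y ~ Bernoulli(z * p)}: an individual not in the population
#' (z = 0) cannot be detected, so y = 1 with z = 0 has probability zero
#' (-Inf log-likelihood, flagging an inconsistent latent state).
#'
#' @param y 0/1 detection indicator(s).
#' @param z 0/1 presence state(s).
#' @param p detection probabilities.
#' @return Sum of Bernoulli log-masses.
#' @export
observation_loglik <- function(y, z, p) {
  stopifnot(all(y %in% c(0, 1)), all(z %in% c(0, 1)),
            all(p >= 0), all(p <= 1))
  pr <- z * p
  sum(ifelse(y == 1, log(pr), log1p(-pr)))
}
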