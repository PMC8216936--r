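#' Distances from an activity center to every pixel
#'
#' Euclidean distances between the center of the activity-center pixel and
#' every valid pixel center of the grid.
#'
#' @param s_pixel activity-center pixel index.
#' @param grid an [ss_grid()] object.
#' @return Numeric vector of length \code{grid$G}; zero at \code{s_pixel}.
#' @export
center_pixel_distances <- function(s_pixel, grid) {
  stopifnot(s_pixel >= 1, s_pixel <= grid$G)
  sqrt((grid$centers[, 1] - grid$centers[s_pixel, 1])^2 +
         (grid$centers[, 2] - grid$centers[s_pixel, 2])^2)
}

# G x G matrix of squared center-to-center distances (rows = from)
pixel_dist2_matrix <- function(grid) {
  cx <- grid$centers[, 1]; cy <- grid$centers[, 2]
  outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2
}

#' Space-use (movement) distribution around an activity center
#'
#' Probability that an individual anchored at activity-center pixel
#' \code{s_pixel} occupies each pixel on a secondary occasion. The
#' log-kernel combines a Gaussian decay with distance from the activity
#' center and a habitat (resource-selection) term sharing the density
#' model's coefficients:
#' \code{log mu_g = -d_g^2 / (2 sigma_move^2) + sum_j beta_j X_jgt},
#' normalized over pixels. Space use is therefore neither symmetric nor
#' unconstrained: habitat can pull use away from the center and unsuitable
#' pixels (excluded from the grid) are never occupied. Evaluated on the log
#' scale with max-subtraction so small \code{sigma_move} cannot underflow.
#'
#' @param s_pixel activity-center pixel index.
#' @param sigma_move positive movement scale (distance units).
#' @param beta habitat coefficients (length J); use zeros for a
#'   habitat-free kernel.
#' @param X G x J x T covariate array.
#' @param t primary-period index.
#' @param grid an [ss_grid()] object.
#' @return Length-G simplex.
#' @export
pi_movement <- function(s_pixel, sigma_move, beta, X, t, grid) {
  stopifnot(sigma_move > 0, dim(X)[1] == grid$G)
  d <- center_pixel_distances(s_pixel, grid)
  lw <- -d^2 / (2 * sigma_move^2) + density_linpred(beta, X, t)
  w <- exp(lw - max(lw))
  w / sum(w)
}

# all-activity-center version: G x G matrix of log movement probabilities,
# row g0 = log pi_movement(s = g0); D2 from pixel_dist2_matrix(), eta the
# period's covariate linear predictor
log_movement_matrix <- function(D2, eta, sigma_move) {
  lw <- -D2 / (2 * sigma_move^2) + rep(eta, each = nrow(D2))
  mx <- lw[cbind(seq_len(nrow(lw)), max.col(lw))]
  lw <- lw - mx
  lw - log(rowSums(exp(lw)))
}

#' Sample an occasion location
#'
#' Draw a latent location for one secondary occasion: a pixel from the
#' space-use distribution, then exact coordinates uniform within that
#' pixel's square.
#'
#' @param pi_movement length-G simplex (see [pi_movement()]).
#' @param grid an [ss_grid()] object.
#' @param n number of independent locations to draw.
#' @return A list with integer \code{pixel} and numeric \code{x}, \code{y}
#'   (each length \code{n}).
#' @export
sample_location <- function(pi_movement, grid, n = 1) {
  g <- sample.int(grid$G, n, replace = TRUE, prob = pi_movement)
  half <- grid$side / 2
  list(pixel = g,
       x = grid$centers[g, 1] + stats::runif(n, -half, half),
       y = grid$centers[g, 2] + stats::runif(n, -half, half))
}
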