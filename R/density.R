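#' Build a standardized habitat-covariate stack
#'
#' Assemble per-pixel, per-period covariate values into the G x J x T array
#' used by the density and movement models. Each covariate is standardized
#' to mean 0, sd 1 pooling over all pixels and periods. Squared companion
#' columns (for modeling dome-shaped responses, e.g. a thermal optimum) are
#' formed by squaring the already-standardized base column and then
#' standardizing the square as well, so every column of the stack is on a
#' common scale; the density model itself stays strictly linear in the
#' supplied columns.
#'
#' @param x a G x J x T numeric array, or a G x J matrix (replicated across
#'   periods) of raw covariate values.
#' @param names character vector of J covariate names.
#' @param T_periods number of primary periods (needed when \code{x} is a
#'   matrix).
#' @param square names (or indices) of covariates that get a squared
#'   companion column, appended as \code{"<name>2"}.
#' @param standardize standardize columns (default TRUE; set FALSE if the
#'   input is already standardized).
#' @return A G x J' x T array of class \code{"scr_covariates"} with
#'   covariate names in \code{dimnames[[2]]}.
#' @export
covariate_stack <- function(x, names = NULL, T_periods = NULL,
                            square = NULL, standardize = TRUE) {
  if (is.matrix(x)) {
    if (is.null(T_periods)) stop("T_periods required for matrix input")
    x <- array(rep(x, T_periods), dim = c(nrow(x), ncol(x), T_periods),
               dimnames = list(NULL, colnames(x), NULL))
  }
  stopifnot(length(dim(x)) == 3)
  if (is.null(names)) names <- dimnames(x)[[2]]
  if (is.null(names)) names <- paste0("cov", seq_len(dim(x)[2]))
  J <- dim(x)[2]
  stopifnot(length(names) == J)
  if (!all(is.finite(x))) stop("covariate values must be finite")
  std1 <- function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s < 1e-12)
      stop("degenerate covariate: no variation over pixels and periods")
    (v - mean(v)) / s
  }
  if (standardize) for (j in seq_len(J)) x[, j, ] <- std1(x[, j, ])
  if (length(square)) {
    if (is.character(square)) square <- match(square, names)
    if (anyNA(square)) stop("unknown covariate name in 'square'")
    sq <- x[, square, , drop = FALSE]^2
    if (standardize) for (j in seq_along(square)) sq[, j, ] <- std1(sq[, j, ])
    xx <- array(NA_real_, dim = dim(x) + c(0, length(square), 0))
    xx[, seq_len(J), ] <- x
    xx[, J + seq_along(square), ] <- sq
    names <- c(names, paste0(names[square], "2"))
    x <- xx
  }
  dimnames(x) <- list(NULL, names, NULL)
  class(x) <- c("scr_covariates", class(x))
  x
}

#' Expected relative density surface
#'
#' Expected density of activity centers per pixel at primary period t,
#' \code{E(D_gt) = exp(sum_j beta_j X_jgt)}. Total abundance is set by the
#' open-population model, so the density model is intercept-free and
#' describes relative density only.
#'
#' @param beta length-J coefficient vector.
#' @param X a G x J x T covariate array (see [covariate_stack()]).
#' @param t primary-period index.
#' @return Positive numeric vector of length G.
#' @export
expected_density <- function(beta, X, t) {
  eta <- density_linpred(beta, X, t)
  exp(eta)
}

# linear predictor sum_j beta_j X[, j, t]; shared by density and movement
density_linpred <- function(beta, X, t) {
  stopifnot(length(beta) == dim(X)[2], t >= 1, t <= dim(X)[3])
  m <- matrix(X[, , t], dim(X)[1], dim(X)[2])
  drop(m %*% beta)
}

#' Activity-center placement distribution
#'
#' The categorical distribution of activity centers over pixels at period t:
#' expected density normalized to sum to one,
#' \code{pi_g = E(D_gt) / sum_g E(D_gt)}. Computed on the log scale with
#' max-subtraction so extreme coefficients cannot overflow.
#'
#' @inheritParams expected_density
#' @return Numeric simplex of length G (non-negative, sums to 1).
#' @export
pi_density <- function(beta, X, t) {
  eta <- density_linpred(beta, X, t)
  w <- exp(eta - max(eta))
  w / sum(w)
}

#' Sample activity centers
#'
#' Independent categorical draws of pixel indices from an activity-center
#' placement distribution.
#'
#' @param pi_density_t length-G simplex (see [pi_density()]).
#' @param M number of draws (augmented population size).
#' @return Integer vector of length M of pixel indices.
#' @export
sample_activity_centers <- function(pi_density_t, M) {
  stopifnot(all(pi_density_t >= 0), abs(sum(pi_density_t) - 1) < 1e-6)
  sample.int(length(pi_density_t), M, replace = TRUE, prob = pi_density_t)
}

#' Realized absolute density
#'
#' Number of activity centers of individuals present in each pixel at
#' period t, divided by pixel area: the realized density surface for one
#' state of the population (or one posterior draw). The area-weighted sum
#' over pixels equals abundance N_t exactly.
#'
#' @param z M x T presence matrix.
#' @param s M x T matrix of activity-center pixel indices.
#' @param grid an [ss_grid()] object.
#' @param t primary-period index.
#' @return Numeric vector of length \code{grid$G} (individuals per unit
#'   area).
#' @export
realized_density <- function(z, s, grid, t) {
  z <- as.matrix(z); s <- as.matrix(s)
  present <- z[, t] == 1
  counts <- tabulate(s[present, t], nbins = grid$G)
  counts / grid$side^2
}
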