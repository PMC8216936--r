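#' Group-membership probabilities from gamma weights
#'
#' The categorical distribution of demographic-group membership is given a
#' noninformative Dirichlet prior specified through independent gamma
#' weights: \code{pi_v = a_v / sum(a)} with \code{a_v ~ Gamma(1, 1)} i.i.d.
#' is exactly a flat Dirichlet(1, ..., 1) on the simplex.
#'
#' @param a positive numeric vector of gamma weights (length V).
#' @return Length-V simplex.
#' @export
pi_group_from_a <- function(a) {
  stopifnot(all(a > 0))
  a / sum(a)
}

#' Sample a latent group index
#'
#' Full-conditional draw of group membership for an individual whose group
#' is unknown: categorical with probability proportional to the prior
#' membership probability times the likelihood of the individual's data
#' under each group's parameters.
#'
#' @param likelihood_by_group non-negative length-V vector, the likelihood
#'   of the individual's data under each group; must not be all zero.
#' @param pi_group length-V membership simplex.
#' @return Integer group index in 1..V.
#' @export
sample_group <- function(likelihood_by_group, pi_group) {
  w <- likelihood_by_group * pi_group
  if (all(w == 0) || any(w < 0) || !all(is.finite(w)))
    stop("impossible state: group likelihoods are all zero or invalid")
  sample.int(length(w), 1, prob = w)
}
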