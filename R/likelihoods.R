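# Count likelihoods used throughout the package.
#
# Negative binomial parameterization (fixed for the whole package):
#   pmf(x; mu, beta) = Gamma(x+beta) / (Gamma(beta) x!) *
#                      (beta/(beta+mu))^beta * (mu/(beta+mu))^x
# with mean mu and variance mu + mu^2/beta; beta is the inverse-dispersion
# (beta -> Inf recovers Poisson).

MU_FLOOR <- 1e-8
BETA_MIN <- 1e-3
BETA_MAX <- 1e4

# expand a per-gene vector to an n x G matrix (R recycling is column-major,
# so plain arithmetic with a length-G vector against an n x G matrix would
# be wrong)
per_gene <- function(v, n, G) matrix(v, n, G, byrow = TRUE)

#' Negative binomial log pmf (mean / inverse-dispersion parameterization)
#'
#' @param x counts (vector or matrix).
#' @param mu means, same shape as `x` (floored at 1e-8).
#' @param beta inverse-dispersion; a scalar, a vector matching `x`, or —
#'   when `x` is an n x G matrix — a length-G per-gene vector.
#' @return elementwise log pmf, same shape as `x`.
#' @export
nb_log_pmf <- function(x, mu, beta) {
  if (is.matrix(x) && !is.matrix(beta) && length(beta) == ncol(x) &&
      ncol(x) > 1) {
    beta <- per_gene(beta, nrow(x), ncol(x))
  }
  mu <- pmax(mu, MU_FLOOR)
  lgamma(x + beta) - lgamma(beta) - lgamma(x + 1) +
    beta * (log(beta) - log(beta + mu)) + x * (log(mu) - log(beta + mu))
}

# d log NB / d mu
nb_dll_dmu <- function(x, mu, beta) {
  if (is.matrix(x) && !is.matrix(beta) && length(beta) == ncol(x) &&
      ncol(x) > 1) {
    beta <- per_gene(beta, nrow(x), ncol(x))
  }
  x / mu - (x + beta) / (beta + mu)
}

#' Poisson log pmf
#' @inheritParams nb_log_pmf
#' @export
poisson_log_pmf <- function(x, mu) {
  dpois(x, lambda = pmax(mu, MU_FLOOR), log = TRUE)
}

#' Zero-inflated negative binomial log pmf
#'
#' Dropout mixture: with probability `tau` the observation is a structural
#' zero, otherwise NB(mu, beta). `tau = 0` reduces exactly to the NB pmf.
#'
#' @inheritParams nb_log_pmf
#' @param tau dropout probability in \[0, 1\]; scalar, matching shape, or
#'   per-gene vector for matrix input.
#' @export
zinb_log_pmf <- function(x, mu, beta, tau) {
  if (is.matrix(x) && !is.matrix(tau) && length(tau) == ncol(x) &&
      ncol(x) > 1) {
    tau <- per_gene(tau, nrow(x), ncol(x))
  }
  if (any(tau < 0 | tau > 1)) stop("tau must lie in [0, 1]", call. = FALSE)
  ll_nb <- nb_log_pmf(x, mu, beta)
  tau <- x * 0 + tau  # broadcast to the shape of x
  out <- log(1 - tau) + ll_nb
  zero <- x == 0
  if (any(zero)) {
    # mixture at zero: log(tau + (1 - tau) * p0) with p0 = NB pmf at x = 0
    out[zero] <- log(tau[zero] + (1 - tau[zero]) * exp(ll_nb[zero]))
  }
  out
}
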